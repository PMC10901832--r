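# Desk-scale run configuration: 48 x 48 x 40 voxels at the 0.106 mm study
# pitch (mm/MHz convenience keys), variable homogeneous sound speed.
scenario: variable_sos
c_recon: 1500.0
train_sos_spec: [1400.0, 1600.0]
test_sos_spec: [1400.0, 1600.0]
n_train: 20
n_test: 5
noise_frac: 0.01
learning_rates: [0.01]
epochs: 6
seed: 1
unet_width: 8
gnet_width: 8
grid:
  nx: 48
  ny: 48
  nz: 40
  nt: 48
  dx_mm: 0.106
  sampling_mhz: 14.150943396
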