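# Full-scale training configuration (multi-GPU scale; not
# runnable at desk scale — see the desk defaults in train_config()).
seed: 1
optical:
  background_level: 500
  psf_extent: 32
scene:
  T: 8
  shape: [512, 512]        # 500x500 sensor padded to the nearest /16
denoiser:
  base_channels: 16
  lstm_hidden_channels: 16
training:
  enabled: true
  n_pairs: 1000            # 1000 differential SPRM sequences
  epochs: 1000             # models saved every 5 epochs
  batch: 32
  lr0: 1.0e-4              # halved every 50 epochs
stages: [simulate, train, denoise, snr]
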