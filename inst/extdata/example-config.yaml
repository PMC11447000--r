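# Example analysis configuration; any key omitted keeps its default.
psd:
  epoch_s: 30
  bin_hz: 2
  band_epoch_s: 10
bands:
  delta: [0.5, 4]
  theta: [4, 8]
  alpha: [8, 12]
  beta: [12, 30]
  gamma: [30, 50]
artifact:
  eeg_mV: 0.2
  emg_mV: 1
spikes:
  threshold_uV: 200
  min_spike_dur_ms: 1
  max_spike_dur_ms: 200
  isi_min_s: 0.05
  isi_max_s: 0.5
  min_spikes_per_train: 3
  min_train_time_s: 1
sleep:
  delta_paradoxical_wake: 0.5
  delta_sws: 1
  theta_wake_sws: 1.3
  theta_paradoxical: 3
  emg_paradoxical_sws: 1
  emg_wake: 2.4
  activity_active_wake: 0.1
  emg_active_wake_factor: 1.5
mea:
  bin_width_s: 0.01
  gaussian_sigma_s: 0.1
  threshold_k: 3
  min_spikes: 50
  min_peak_separation_s: 0.2
  boundary_fraction: 0.1
  scan_duration_s: 30
  network_electrodes: 1024
  assay_duration_s: 300
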