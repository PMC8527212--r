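# Demonstration pipeline configuration: a reduced synthetic study.
# Run with:
#   Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo_config.yaml
seed: 1
fps: 25
simulate:
  n_groups: 4
  days: [1, 3, 6, 9, 12]
  n_intervals: 3
  n_frames: 750          # 30 s per interval block
preprocess:
  max_speed_px_per_frame: 50
  sg_window: 13
  sg_degree: 3
  min_interval_s: 30
metrics:
  polarization_threshold: 0.65
  max_lag_frames: 300
models:
  responses: [polarization, centroid_speed, hull_area]
  bootstrap_reps: 0
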