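# Example trackmorph pipeline configuration.
# Any key omitted here keeps the package default (see default_config()).

video:
  fps: 25          # frames per second of the recording (Hz)
  scale: 1         # micrometres per pixel; calibrate per optics!

segmentation:
  offset: 25       # reference-frame offset (frames); 1 s at 25 fps
  threshold: 40    # gray-value cut; validate with check_threshold_values()
  min_area: 5      # particle area bounds (px^2)
  max_area: 100000
  method: subtract # subtract (default) | abs
  blur_sigma: 0    # optional Gaussian pre-blur (px); 0 = off
  grey_source: difference  # difference | raw

linking:
  link_range: 5    # max frame gap L
  max_disp: 20     # max per-frame displacement (px); 25 for fast swimmers
  gap_mode: linear # linear | fixed gap allowance

filtering:
  min_net: 50             # minimum net displacement (um)
  min_duration: 0.2       # minimum duration (s)
  min_detection_rate: 0.8 # minimum detection rate (fraction)
  min_median_step: 2      # median step must exceed this (um)

io:
  input_dir: videos        # one image-sequence subdirectory per video
  output_dir: trackmorph_out
  description_file: null   # optional CSV with a `file` column + metadata
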