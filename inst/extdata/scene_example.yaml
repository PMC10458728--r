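# Example flight-tunnel rig description (lengths in metres, rates in Hz)
tunnel:
  length: 1.56
  width: 0.28
  height: 0.28
  barrier_x: 1.26        # barrier plane, 0.30 m before the exit
  texture_seed: 1
barrier:
  mode: dynamic          # static | dynamic
  d_min: 0.02
  d_max: 0.10
  pulse_freq: 640        # stepper pulse frequency
  gear_radius: 0.01      # gear indexing-circle radius
  reduction: 64          # gearbox reduction ratio
detector:                # wide-angle trigger camera, 30 fps
  image_size: [310, 72]
  position: [0.55, 0.0, 0.64]
  span_m: 0.62
  fps: 30
framing:                 # high-speed camera over the barrier, 163 fps
  image_size: [500, 288]
  position: [1.26, 0.0, 0.64]
  span_m: 0.50
  fps: 163
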