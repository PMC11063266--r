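# Bundled anatomical-variation distribution for cohort simulation.
# Emulates the qualitative spread seen across real sides: a mass point of
# vertebral-artery hypoplasia, a right-skewed caliber distribution reaching
# gross dilation, symmetric venous dominance, and a spread of CN XI root
# heights. Tuned once so that, at n = 50 under the frozen master seed, the
# optimal-approach frequencies are ordered ITA > TTA > STA with all three
# present, then frozen.
va_radius_mm:
  hypoplasia_prob: 0.12
  hypoplasia_radius: 1.0
  ectasia_prob: 0.09   # dolichoectatic, grossly dilated VA
  ectasia_radius: 6.5
  meanlog: 0.78        # lognormal body, median ~2.2 mm
  sdlog: 0.35
  min: 1.0
  max: 6.5
sinus_dominance:
  shape1: 2.0          # Beta(2, 2): symmetric about 0.5
  shape2: 2.0
cn11_height_mm:
  mean: 0.0
  sd: 3.0
  min: -8.0
  max: 8.0
tubercle_size_mm:
  mean: 9.0
  sd: 1.6
  min: 5.5
  max: 12.0
condyle_size_mm:
  mean: 8.0
  sd: 0.7
  min: 5.5
  max: 9.5
jitter_mm: 0.6
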