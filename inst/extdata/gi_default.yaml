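kge: 8.5
get_h: 0.5
kge_post: 100.0
kt:
- 1.4
- 1.4
- 1.4
- 1.4
k_colon: 1.4
radius_cm: 0.163
peff: 0.00015
water_ml: 240.0
v_basal_ml: 35.0
vol_poly:
- segment: duodenum
  coef:
  - 6.0
  - 46.0952
  - -61.1429
  - 19.0476
- segment: prox_jejunum
  coef:
  - 15.0
  - 75.2381
  - -100.857
  - 31.619
- segment: dist_jejunum
  coef:
  - 12.0
  - 46.0952
  - -61.1429
  - 19.0476
- segment: prox_ileum
  coef:
  - 8.0
  - 23.0476
  - -30.5714
  - 9.52381
- segment: dist_ileum
  coef:
  - 5.0
  - 17.2857
  - -22.9286
  - 7.14286
vol_poly_tmax: 2.0
vol_floor_ml: 1.0
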