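{
  "comment": "Canonical larva region template in unit coordinates (row_frac, col_frac), origin top-left. Scaled to the raster shape by defaultRoiSet(). Yolk: 24-gon ellipse; trunk: elongated tapering body axis to the right of the yolk.",
  "rois": [
    {
      "name": "yolk",
      "unit_vertices": [
        [0.8200, 0.2800], [0.8132, 0.3162], [0.7932, 0.3500], [0.7614, 0.3790],
        [0.7200, 0.4012], [0.6718, 0.4152], [0.6200, 0.4200], [0.5682, 0.4152],
        [0.5200, 0.4012], [0.4786, 0.3790], [0.4468, 0.3500], [0.4268, 0.3162],
        [0.4200, 0.2800], [0.4268, 0.2438], [0.4468, 0.2100], [0.4786, 0.1810],
        [0.5200, 0.1588], [0.5682, 0.1448], [0.6200, 0.1400], [0.6718, 0.1448],
        [0.7200, 0.1588], [0.7614, 0.1810], [0.7932, 0.2100], [0.8132, 0.2438]
      ]
    },
    {
      "name": "trunk",
      "unit_vertices": [
        [0.4000, 0.4400], [0.4200, 0.6000], [0.4400, 0.7500], [0.4700, 0.9500],
        [0.5300, 0.9500], [0.5600, 0.7500], [0.6000, 0.6000], [0.6300, 0.4400]
      ]
    }
  ]
}
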