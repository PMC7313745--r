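# Plate layout schema: all keys understood by readPlateLayout().
# A 110 mm dish imaged at 40 um/px fills ~2750 px; this example describes
# a 1300x1300 px recording of a six-segment dilution plate.
center_row: 650
center_col: 650
dish_radius_px: 620
image_nrow: 1300
image_ncol: 1300
n_segments: 6
rim_inset_mm: 3.0
segment_gap_deg: 4.0
rotation_deg: 0.0
pixel_pitch_um: 40.0
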