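rat_id,n,iou_box_mean,iou_box_sd,iou_mask_mean,iou_mask_sd,certainty_mean,certainty_sd
R1,637,82.27,7.73,86.86,6.18,99.84,0.40
R2,654,82.85,6.01,88.28,4.61,99.90,0.26
R3,659,82.42,6.37,88.09,4.39,99.80,1.69
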