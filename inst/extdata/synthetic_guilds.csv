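"taxon","guild"
"t0004","herbivore"
"t0006","predator"
"t0009","predator"
"t0013","herbivore"
"t0015","unassigned"
"t0017","unassigned"
"t0019","herbivore"
"t0020","detritivore_fungivore"
"t0021","generalist"
"t0023","generalist"
"t0024","predator"
"t0027","herbivore"
"t0030","detritivore_fungivore"
"t0032","herbivore"
"t0033","generalist"
"t0034","detritivore_fungivore"
"t0036","unassigned"
"t0037","herbivore"
"t0038","generalist"
"t0041","herbivore"
"t0044","predator"
"t0046","generalist"
"t0047","detritivore_fungivore"
"t0050","herbivore"
"t0051","herbivore"
"t0053","generalist"
"t0054","herbivore"
"t0055","generalist"
"t0056","unassigned"
"t0057","herbivore"
"t0059","herbivore"
"t0063","herbivore"
"t0066","detritivore_fungivore"
"t0068","detritivore_fungivore"
"t0070","generalist"
"t0072","predator"
"t0078","detritivore_fungivore"
"t0081","herbivore"
"t0082","predator"
"t0086","herbivore"
"t0087","unassigned"
"t0088","herbivore"
"t0089","herbivore"
"t0090","herbivore"
"t0093","unassigned"
"t0094","detritivore_fungivore"
"t0100","unassigned"
"t0101","herbivore"
"t0102","generalist"
"t0105","detritivore_fungivore"
"t0106","herbivore"
"t0107","herbivore"
"t0109","predator"
"t0115","unassigned"
"t0116","herbivore"
"t0120","detritivore_fungivore"
"t0121","detritivore_fungivore"
"t0127","unassigned"
"t0129","predator"
"t0134","predator"
"t0135","detritivore_fungivore"
"t0136","detritivore_fungivore"
"t0138","predator"
"t0140","herbivore"
"t0141","detritivore_fungivore"
"t0144","generalist"
"t0147","generalist"
"t0149","generalist"
"t0151","herbivore"
"t0152","herbivore"
"t0153","herbivore"
"t0154","herbivore"
"t0155","herbivore"
"t0156","herbivore"
"t0161","herbivore"
"t0164","detritivore_fungivore"
"t0165","herbivore"
"t0168","detritivore_fungivore"
"t0170","generalist"
"t0171","predator"
"t0174","generalist"
"t0178","predator"
"t0179","herbivore"
"t0181","generalist"
"t0185","herbivore"
"t0186","detritivore_fungivore"
"t0188","unassigned"
"t0191","herbivore"
"t0192","predator"
"t0194","herbivore"
"t0195","unassigned"
"t0197","generalist"
"t0199","generalist"
"t0200","predator"
"t0201","generalist"
"t0203","herbivore"
"t0205","generalist"
"t0209","herbivore"
"t0210","herbivore"
"t0216","generalist"
"t0219","herbivore"
"t0220","generalist"
"t0230","unassigned"
"t0231","detritivore_fungivore"
"t0234","herbivore"
"t0236","predator"
"t0237","detritivore_fungivore"
"t0239","generalist"
"t0240","herbivore"
"t0241","herbivore"
"t0243","herbivore"
"t0245","predator"
"t0246","generalist"
"t0250","predator"
"t0253","detritivore_fungivore"
"t0254","detritivore_fungivore"
"t0257","detritivore_fungivore"
"t0261","herbivore"
"t0262","unassigned"
"t0263","predator"
"t0269","herbivore"
"t0273","herbivore"
"t0274","unassigned"
"t0275","detritivore_fungivore"
"t0278","herbivore"
"t0279","detritivore_fungivore"
"t0281","predator"
"t0285","herbivore"
"t0286","predator"
"t0294","herbivore"
"t0295","herbivore"
"t0299","unassigned"
"t0303","herbivore"
"t0304","unassigned"
"t0305","herbivore"
"t0307","predator"
"t0308","generalist"
"t0311","detritivore_fungivore"
"t0317","herbivore"
"t0323","generalist"
"t0330","herbivore"
"t0331","herbivore"
"t0335","predator"
"t0337","herbivore"
"t0338","generalist"
"t0341","predator"
"t0344","predator"
"t0351","herbivore"
"t0360","generalist"
"t0361","herbivore"
"t0372","herbivore"
"t0379","generalist"
"t0382","unassigned"
"t0383","generalist"
"t0384","detritivore_fungivore"
"t0386","herbivore"
"t0389","detritivore_fungivore"
"t0393","herbivore"
"t0396","herbivore"
"t0402","herbivore"
"t0403","detritivore_fungivore"
"t0404","unassigned"
"t0408","herbivore"
"t0409","detritivore_fungivore"
"t0411","herbivore"
"t0414","predator"
"t0421","herbivore"
"t0427","unassigned"
"t0432","herbivore"
"t0433","generalist"
"t0437","unassigned"
"t0438","herbivore"
"t0445","herbivore"
"t0446","detritivore_fungivore"
"t0447","generalist"
"t0448","detritivore_fungivore"
"t0452","herbivore"
"t0453","herbivore"
"t0455","predator"
"t0460","generalist"
"t0462","unassigned"
"t0465","predator"
"t0469","unassigned"
"t0471","detritivore_fungivore"
"t0476","herbivore"
"t0483","detritivore_fungivore"
"t0485","herbivore"
"t0491","predator"
"t0502","herbivore"
"t0503","herbivore"
"t0506","herbivore"
"t0507","generalist"
"t0515","unassigned"
"t0517","herbivore"
"t0521","generalist"
"t0523","herbivore"
"t0525","herbivore"
"t0530","herbivore"
"t0532","herbivore"
"t0534","herbivore"
"t0536","detritivore_fungivore"
"t0541","predator"
"t0543","predator"
"t0544","unassigned"
"t0551","generalist"
"t0564","detritivore_fungivore"
"t0566","herbivore"
"t0571","herbivore"
"t0577","herbivore"
"t0578","herbivore"
"t0587","unassigned"
"t0588","generalist"
"t0596","detritivore_fungivore"
"t0599","predator"
"t0603","unassigned"
"t0604","herbivore"
"t0615","herbivore"
"t0618","herbivore"
"t0620","generalist"
"t0644","herbivore"
"t0648","herbivore"
"t0655","unassigned"
"t0657","generalist"
"t0659","generalist"
"t0671","predator"
"t0672","detritivore_fungivore"
"t0676","unassigned"
"t0679","generalist"
"t0680","predator"
"t0681","detritivore_fungivore"
"t0685","predator"
"t0687","herbivore"
"t0710","detritivore_fungivore"
"t0714","generalist"
"t0716","detritivore_fungivore"
"t0726","herbivore"
"t0727","generalist"
"t0743","herbivore"
"t0746","herbivore"
"t0756","generalist"
"t0765","detritivore_fungivore"
"t0769","herbivore"
"t0770","predator"
"t0780","detritivore_fungivore"
"t0804","unassigned"
"t0808","unassigned"
"t0818","herbivore"
"t0829","generalist"
"t0832","herbivore"
"t0834","generalist"
"t0835","predator"
"t0842","herbivore"
"t0846","herbivore"
"t0871","herbivore"
"t0872","predator"
"t0873","herbivore"
"t0878","herbivore"
"t0884","herbivore"
"t0902","herbivore"
"t0903","predator"
"t0909","detritivore_fungivore"
"t0910","herbivore"
"t0917","predator"
"t0921","generalist"
"t0928","detritivore_fungivore"
"t0930","predator"
"t0934","herbivore"
"t0941","predator"
"t0944","detritivore_fungivore"
"t0945","generalist"
"t0952","detritivore_fungivore"
"t0960","unassigned"
"t0965","detritivore_fungivore"
"t0968","herbivore"
"t0977","detritivore_fungivore"
"t0986","generalist"
"t0990","unassigned"
"t0992","herbivore"
"t1000","herbivore"
"t1001","herbivore"
"t1008","herbivore"
"t1009","unassigned"
"t1040","predator"
"t1043","predator"
"t1047","herbivore"
"t1056","unassigned"
"t1060","generalist"
"t1067","predator"
"t1068","detritivore_fungivore"
"t1069","generalist"
"t1075","herbivore"
"t1081","herbivore"
"t1098","predator"
"t1108","generalist"
"t1115","predator"
"t1129","generalist"
"t1137","herbivore"
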