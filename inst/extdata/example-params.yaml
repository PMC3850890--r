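# Example parameter file for a batch run with nucleus-derived markers.
# Keys may be written dotted (as here) or as nested sections; unspecified
# keys keep their defaults, and unknown keys are rejected.
segmentation: segmsurf
nchannels: 2
segmplane: 1
illum: 0
smoothim.method: dirced
segmsurf.filterridges: 1
segmsurf.getminima.method: nucleus
segmsurf.getminima.nucleus.thrs.th: 1.0
segmsurf.getminima.nucleus.split: 1
segmsurf.getminima.nucleus.splitth: 1.0
segmsurf.classifycells.method: minimacell
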