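# Named acquisition profiles of the evaluated parameter grid.
# a-d: GRE at increasing TE; e-h: bSSFP at increasing TE.
# Variants: slice thickness 10 mm and parallel phase encoding apply to the
# baseline of either sequence family.  Bandwidth is metadata only.
a: {sequence: GRE,   te: 2.48, tr: 4.6,  flipAngle: 12, sliceThickness: 5, ped: perpendicular, frameRate: 3.3, bandwidth: 1445}
b: {sequence: GRE,   te: 2.54, tr: 4.8,  flipAngle: 12, sliceThickness: 5, ped: perpendicular, frameRate: 3.3, bandwidth: 990}
c: {sequence: GRE,   te: 3.05, tr: 5.8,  flipAngle: 12, sliceThickness: 5, ped: perpendicular, frameRate: 3.3, bandwidth: 505}
d: {sequence: GRE,   te: 6.49, tr: 12.1, flipAngle: 12, sliceThickness: 5, ped: perpendicular, frameRate: 3.3, bandwidth: 130}
e: {sequence: bSSFP, te: 1.47, tr: 2.9,  flipAngle: 39, sliceThickness: 5, ped: perpendicular, frameRate: 5.0, bandwidth: 1510}
f: {sequence: bSSFP, te: 1.54, tr: 3.1,  flipAngle: 39, sliceThickness: 5, ped: perpendicular, frameRate: 5.0, bandwidth: 990}
g: {sequence: bSSFP, te: 1.96, tr: 3.9,  flipAngle: 39, sliceThickness: 5, ped: perpendicular, frameRate: 5.0, bandwidth: 505}
h: {sequence: bSSFP, te: 4.85, tr: 9.6,  flipAngle: 39, sliceThickness: 5, ped: perpendicular, frameRate: 5.0, bandwidth: 130}
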