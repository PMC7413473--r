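# vtk DataFile Version 3.0
minimal externally written rectilinear field
ASCII
DATASET RECTILINEAR_GRID
DIMENSIONS 3 2 1
X_COORDINATES 3 double
0.0 0.5 1.0
Y_COORDINATES 2 double
0.0 1.0
Z_COORDINATES 1 double
0
POINT_DATA 6
VECTORS velocity double
0.1 0 0
0.2 0 0
0.3 0 0
0.1 0 0
0.2 0 0
0.3 0 0
SCALARS mask int 1
LOOKUP_TABLE default
1 1 1 1 1 1
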