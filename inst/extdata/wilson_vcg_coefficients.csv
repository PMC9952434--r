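# Wilson-tetrahedron -> orthogonal vectorcardiogram transform coefficients.
# Transcribed from the published updated-coefficient form of the Wilson
# 4-electrode transform: the unnormalized dipole projection is
#   (vp_x, vp_y, vp_z) = matrix_scale * M * (VL-VR, VF-VR, VB-VR)
# with M the 3x3 matrix below (row-major m11..m33); direction cosines are the
# unit-normalized vp. The per-sample gain is
#   K = k_scale * sqrt(k_e2_coeff * E^2 + k_vb_coeff * VB^2)
# with E^2 = (VL-VR)^2 + e2_cross_coeff * ((VF-VR) + (VF-VL))^2,
# and the orthogonal components are (Vx, Vy, Vz) = 3 * K * (px, py, pz).
# Kept as data (not code) so a corrected transcription is a data change.
name,value
m11,7
m12,-20
m13,-26
m21,55
m22,15
m23,-30
m31,-5
m32,21
m33,39
matrix_scale,0.045454545454545456
k_scale,0.030303030303030304
k_e2_coeff,8
k_vb_coeff,1
e2_cross_coeff,0.3333333333333333
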