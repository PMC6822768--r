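# Synthetic parameter registry for the four-gene circadian clock SDE model
# (genes LHY, TOC1, X, Y; dark condition).
#
# SYNTHETIC VALUES: these constants were NOT taken from any published
# parameter fit.  They were chosen for this package so that the noiseless
# twelve-equation system has bounded, nonnegative dynamics with the LHY-X
# positive-feedback pair settled at a stable high state and the TOC1-Y
# negative-feedback loop in sustained oscillation (period about 11 model
# hours), which is what the reconstruction benchmark requires.  Replace
# this file with a fitted registry to study a calibrated model;
# locke_params() accepts any file in this key = value format.
#
# Units: abundances are arbitrary concentration units, time is in model
# hours; n/m are maximal production/degradation rates (conc/hour), g/k are
# half-saturation constants (conc), p/r are linear rates (1/hour), a..f are
# dimensionless Hill exponents.

# transcription maxima
n1 = 1.2
n2 = 3.02
n3 = 1.2
n4 = 1     # reserved (unused by the dark-condition drifts)
n5 = 2.12

# activation / repression thresholds
g1 = 0.15
g2 = 0.0633
g3 = 19.3
g4 = 0.15
g5 = 0.12
g6 = 19.3

# Michaelis constants of degradation
k1 = 1
k2 = 1
k3 = 1
k4 = 0.194
k5 = 0.2
k6 = 0.2
k7 = 1
k8 = 1
k9 = 1
k10 = 0.0938
k11 = 0.2
k12 = 0.2

# maximal degradation rates
m1 = 2.2
m2 = 0.4
m3 = 0.5
m4 = 1.22
m5 = 0.131
m6 = 0.131
m7 = 0.182
m8 = 0.182
m9 = 2.2
m10 = 0.4
m11 = 0.5
m12 = 1.84
m13 = 0.262
m14 = 0.363

# translation rates
p1 = 0.6
p2 = 0.471
p3 = 0.6
p4 = 0.471

# nuclear transport rates (forward / back)
r1 = 1.5
r2 = 0.2
r3 = 1.33
r4 = 0.224
r5 = 1.5
r6 = 0.2
r7 = 1.33
r8 = 0.224

# Hill exponents
a = 4
b = 4
c = 2
d = 4
e = 4
f = 2
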