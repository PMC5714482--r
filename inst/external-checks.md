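# Optional external cross-checks

The published analyses below use classical datasets whose full mutant
counts are not bundled with this package.  They are therefore *optional*
cross-checks: users who have those datasets available (they circulate with
established fluctuation-assay software) can verify that this
implementation reproduces the published numbers.  They are not part of the
automated test suite.

With `demerec.data` (Demerec 1945; N0 = 90, Nt = 1.9e8):

| quantity                                   | published value          |
|--------------------------------------------|--------------------------|
| ML estimate of m (Lea-Coulson)             | 10.84383                 |
| 95% likelihood-ratio C.I. for m            | (8.650538, 13.194765)    |
| ML estimate of m at phi = 0.9              | 18.92394                 |
| gamma-mixture (cv = 0.15) estimate of m0   | 11.09696                 |
| gamma-mixture 95% C.I.                     | (8.765365, 13.665749)    |

Equivalent calls here: `fit_m(demerec)`, `ci_m(demerec)`,
`fit_m(demerec, phi = 0.9)`, `fit_m(demerec, family = "B0", cv = 0.15)`,
`ci_m(demerec, family = "B0", cv = 0.15)`.

With `cairns.foster.data` (Cairns & Foster 1991):

| quantity                                   | published value          |
|--------------------------------------------|--------------------------|
| joint ML estimate of (m, w)                | (1.3027909, 0.7281044)   |
| profile 95% C.I. for m                     | (0.9855115, 1.6749828)   |
| profile 95% C.I. for w                     | (0.5209636, 1.0298620)   |
| ML estimate of m with w fixed at 0.73      | 1.30215                  |

Equivalent calls here: `fit_mw(cairns_foster)`,
`ci_profile(cairns_foster, "m")`, `ci_profile(cairns_foster, "w")`,
`fit_m(cairns_foster, family = "MK", w = 0.73)`.

With `recent.expt` (plating efficiency 0.01): ML estimate 15.36162 under
perfect-plating assumptions; Stewart-adjusted estimate
15.36 x 21.50 = 330.24 versus the full plating-model ML estimate 593.6 —
the example showing that the Stewart correction understates m.

With `wh.data` (Werngren & Hoffner 2003; epsilon = 0.4 in both experiments,
R = 1.3/2.3): plating-model likelihood-ratio test statistic 0.2435538,
p-value 0.6216511, via
`lrt_rate_equality(wh1, wh3, R = 1.3/2.3, epsilon1 = 0.4, epsilon2 = 0.4)`.
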