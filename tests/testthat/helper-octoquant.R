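# Shared fixtures, built in code at test time.

# Peaks sampled exactly from the two-way decay model.
make_decay_peaks <- function(mu, i0 = 1, c0 = 0.01, z0 = 0.12,
                             spacing = 0.081, n = 26) {
  z <- z0 + (seq_len(n) - 1) * spacing
  I <- (i0 - c0) * exp(-2 * mu * (z - z0)) + c0
  peak_set(z, I, seq_along(z))
}

# Standard layered speckled phantom image for pipeline tests: 500 lateral
# columns, interface period 27 px (0.081 mm, grid-commensurate).
make_layered_bscan <- function(mu, seed, speckle = TRUE,
                               noise_sigma = 0.001, cols = 500L) {
  tr <- ground_truth(mu = mu, i0 = 1, c0 = 0.01, z0 = 0.12,
                     speckle = speckle, noise_sigma = noise_sigma,
                     seed = seed)
  gen_bscan(tr, shape = c(1000L, cols), axial_pitch = 0.003,
            layer_period = 0.081)
}

wide_roi_config <- function(cols = 500L) {
  run_config(roi = roi_spec(0, cols, 40, 900))
}

# Frozen oracle values for the Lorenz-Mie series: q_sca and asymmetry g
# computed with an independent direct Riccati-Bessel implementation
# (scipy.special spherical_jn/yn route, no logarithmic derivative).
mie_oracle_grid <- function() {
  read.csv(text = "x,m,q_sca,g
0.1,1.05,2.9005816066e-07,1.6308633939e-03
0.1,1.125,1.7595462125e-06,1.6791633427e-03
0.1,1.33,1.1090625362e-05,1.8319588209e-03
0.1,1.5,2.3084093579e-05,1.9817737650e-03
0.5,1.05,1.6675951877e-04,4.1151756419e-02
0.5,1.125,1.0287903196e-03,4.2155975480e-02
0.5,1.33,6.7731398838e-03,4.5464781761e-02
0.5,1.5,1.4566628236e-02,4.8866044181e-02
1,1.05,2.0564541020e-03,1.6887218914e-01
1,1.125,1.3112557198e-02,1.7222481076e-01
1,1.33,9.3924001214e-02,1.8451667398e-01
1,1.5,2.1509759604e-01,1.9894249464e-01
2,1.05,1.4083534067e-02,6.2287908099e-01
2,1.125,9.0897064830e-02,6.4433571916e-01
2,1.33,7.1294832186e-01,6.6972169151e-01
2,1.5,1.7984181632e+00,6.2595314612e-01
5,1.05,1.1821678876e-01,9.0825413616e-01
5,1.125,7.4014378841e-01,9.0434879048e-01
5,1.33,3.5910329236e+00,8.4534044109e-01
5,1.5,3.9278267316e+00,7.0729478402e-01
5.983986,1.125,1.0453136995e+00,9.2308552951e-01
10,1.05,4.8352872572e-01,9.6970653575e-01
10,1.33,2.2065487102e+00,7.1245926967e-01
10,1.5,2.8819989521e+00,7.4291289857e-01")
}
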