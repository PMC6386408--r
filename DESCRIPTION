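Package: softsweeps
Title: Spatial Soft Sweeps on Lattices with Long-Range Dispersal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation and analysis of spatial soft sweeps in
    stepping-stone populations with fat-tailed (power-law) dispersal kernels.
    Provides a compiled event loop for deme-lattice sweeps under allelic
    exclusion, solitary-clone growth simulations and the core-growth function
    ell(t), characteristic length scales from mutation-expansion balance
    (core extent chi, satellite extent psi, rare-jump limit zeta), per-clone
    geometry (mass-equivalent radius, extent, occupancy profiles), allele
    frequency spectra with scaling collapse and power-law ansatz fits, and
    global and local sampling statistics (hard-sweep probabilities, subrange
    homoallelicity, Ewens sampling limit).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
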