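Package: ambusim
Title: Spatial-Epidemiological Modelling of Emergency Ambulance Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the effect, in lives saved or lost per year, of
    introducing an emergency ambulance service in a region. Combines
    least-cost-path travel-time surfaces computed over road-friction
    rasters, a density-dependent Rayleigh model of the delay in arranging
    informal transport, an exponential survival model for time-critical
    conditions, and Monte Carlo propagation of parameter uncertainty.
    Produces credible intervals for total lives saved, per-cell
    lives-saved maps, and maps of the probability that an ambulance beats
    informal transport. Includes a synthetic-data generator (clustered
    towns, road networks, facilities) so the whole pipeline runs without
    external downloads, and a minimal single-band GeoTIFF reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
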