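Package: broodopt
Title: Optimal Brood Size in Stochastic Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for life-history analysis of optimal brood (clutch, litter,
    seed-set) size under demographic and environmental stochasticity. Couples
    von Bertalanffy juvenile growth with size-dependent juvenile mortality and
    brood-cost adult mortality to give a discrete-time linear population map,
    and computes long-run growth rates as Lyapunov exponents when brood size
    varies across individuals (Poisson) or when resource availability varies
    across years (lognormal, e.g. mast seeding). Includes per-year (plastic)
    brood-size optimization synchronized to resource availability, comparison
    of plastic versus constant strategies, and a two-environment translocation
    analysis contrasting a masting-adapted species with one adapted to a
    constant environment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
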