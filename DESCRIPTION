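Package: ltcisim
Title: System-Dynamics Simulation of Long-Term Care Insurance Fund Financing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic annual stock-flow simulator of a municipal
    long-term care insurance (LTCI) fund financed by individual premiums,
    enterprise contributions, and government subsidies. Projects fund
    revenue, expenditure, and balance over a 2019-2030 horizon from
    yearbook-style demographic and economic drivers; runs policy-lever
    scenario batteries (payment rates, reimbursement ratio, severe
    disability rate); calibrates the expenditure escalation rate against a
    scenario anchor in closed form; validates against historical series via
    signed percent errors; and performs uniform Monte-Carlo sensitivity
    analysis with per-year balance envelopes. Includes a generator of
    synthetic yearbook-like series for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
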