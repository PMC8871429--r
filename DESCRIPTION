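Package: gelosmo
Title: Osmotic and Scattering Thermodynamics of Polyelectrolyte Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decompose measured swelling pressures of polymer and
    polyelectrolyte hydrogels into elastic, mixing and ionic (Donnan)
    contributions, extract second and third osmotic virial coefficients from
    deswelling curves, map Flory-Huggins interaction parameters to virial
    coefficients, predict equilibrium swelling and salt-induced volume
    transitions, estimate the longitudinal osmotic modulus, fit small-angle
    neutron scattering profiles with a two-component (Ornstein-Zernike plus
    power-law) intensity model, and cross-check osmotic against scattering
    estimates of the concentration-fluctuation amplitude. Includes a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
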