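Package: lpamr
Title: One-Sample Mendelian Randomization of Lipoprotein(a), Vascular
    Superoxide, and Cardiovascular Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested analysis chain for one-sample cis-Mendelian
    randomization of plasma lipoprotein(a) against vascular redox state and
    cardiovascular death in a surgical cohort design: genotype input (VCF
    subset or dosage tables), per-variant quantitative-trait association and
    an unweighted 7-SNP LPA genetic risk score, two-locus EM haplotype
    estimation with D'/r2 linkage statistics, derived superoxide bioassay
    indices (L-NAME delta, NADPH/Vas2870 contrasts, BH4/BH2 ratio), an
    implemented-from-scratch statistical core (two-group tests, rank
    correlations, standardized-beta linear models with Levene-triggered
    bootstrap, moderation, Cox partial-likelihood fitting with Efron ties,
    Wald utilities, Benjamini-Hochberg FDR, power), instrument validation
    (first-stage F, MR-Egger pleiotropy intercept), causal effect estimation,
    and mediation of the survival effect through arterial superoxide. A
    seeded synthetic cohort generator with the assumed causal structure makes
    every stage testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
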