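Package: metapep
Title: Peptide-Centred Metaproteome Profiling of the Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Metapep", "Developers", email = "metapep@example.org",
           role = c("aut", "cre"))
Description: Tools for spectral-count metaproteomics of faecal (gut
    microbiome) samples: lowest-common-ancestor taxonomic assignment of
    tryptic peptides with isoleucine/leucine equating and missed-cleavage
    combining, functional profiling by KEGG Orthology (KO) and COG
    categories, detection and quantification of gut metabolic modules
    (GMM) from KO abundances, bootstrap rarefaction of accumulated and
    core (shared) functions across individuals, and the comparative
    statistics used to characterise personalised, temporally stable
    functional microbiomes (Jaccard and correlation-based hierarchical
    clustering, Spearman correlation screens with false-discovery-rate
    control, Fisher exact group tests, Shannon diversity, and
    proteome-versus-16S phylum concordance). Includes a synthetic cohort
    generator so the entire pipeline can run and be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pheatmap
Config/testthat/edition: 3
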