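# Shared fixtures: the packaged tables, loaded once per test run.
ref_tab <- load_reference_summaries()
meta_tab <- load_species_metadata()
species_tab <- ref_tab[ref_tab$species_code != "Typical", ]
typical_row <- ref_tab[ref_tab$species_code == "Typical", ]

# A three-species miniature summary table for cheap cohort work.
mini_ref <- ref_tab[ref_tab$species_code %in%
                      c("Ca4", "KL", "D5", "Typical"), ]

typical_primaries <- data.frame(IL = 216.42, L1U = 12.66, L2M = 26.45,
                                CHI = 51.59, CLI = 98.17)

# A sample whose mean and SD equal the typical constants exactly for every
# measure (two points at mu +/- sd/sqrt(2)).
typical_like_sample <- local({
  cst <- chelal_constants()
  mu <- cst$typical_mean
  sg <- cst$typical_sd
  out <- data.frame(rbind(mu + sg / sqrt(2), mu - sg / sqrt(2)))
  names(out) <- names(mu)
  out
})
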