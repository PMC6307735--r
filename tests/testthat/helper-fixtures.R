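# shared fixture constructors (built in code; no data files)

quick_sample <- function(id = "S1", group = "ACE", horn = "AGA",
                         tissue = "brain_cortex", net_mg = 50) {
  data.frame(sample_id = id, fetus_id = paste0(id, "_f"), mother_id = "M1",
             group = group, horn = horn, tissue = tissue,
             rotor_total_weight_mg = 550 + 2.22 + net_mg,
             d2o_weight_mg = 2.22, net_tissue_weight_mg = net_mg,
             birthweight_g = if (horn == "FGR") 34.9 else 47.2,
             placental_weight_g = 5.5, stringsAsFactors = FALSE)
}

# small manifest: n per horn for one group/tissue pair plus CTR references
quick_manifest <- function(n_per_horn = 6, n_ctr = 6, group = "ACE",
                           tissue = "brain_cortex") {
  rows <- list()
  for (i in seq_len(n_per_horn)) {
    rows[[length(rows) + 1]] <- quick_sample(sprintf("%s_AGA%02d", group, i),
                                             group, "AGA", tissue)
    rows[[length(rows) + 1]] <- quick_sample(sprintf("%s_FGR%02d", group, i),
                                             group, "FGR", tissue)
  }
  for (i in seq_len(n_ctr)) {
    rows[[length(rows) + 1]] <- quick_sample(sprintf("CTR%02d", i), "CTR",
                                             "AGA", tissue)
  }
  do.call(rbind, rows)
}
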