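# data.table NSE column names used across the package
utils::globalVariables(c(
  "bc1", "bc2", "bc3", "bc1_idx", "bc2_idx", "bc3_idx", "status",
  "read_id", "category", "cell", "cell_id", "feature_id", "umi",
  "truth_cell", "called_cell", "outcome", "group", "captured",
  "miscorrected", "capture_rate", "miscorrection_rate", "degree",
  "count", "n", "N"))

# enable data.table evaluation semantics inside this package
.datatable.aware <- TRUE
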