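# Hand-built event tables for rule-level tests. Dates are expressed as
# day offsets from a fixed origin so traces stay readable.
D0 <- as.Date("2005-01-01")

rx <- function(days, drug, class = "ANTIDEPRESSANT", patient = "p1") {
  n <- length(days)
  data.frame(
    patient_id = rep_len(patient, n),
    issue_date = D0 + days,
    drug_id = rep_len(drug, n),
    drug_class = rep_len(class, n),
    raw_code = rep_len("", n),
    stringsAsFactors = FALSE
  )
}

rx_bind <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

dx <- function(days, category, code = "X", patient = "p1") {
  n <- length(days)
  data.frame(
    patient_id = rep_len(patient, n),
    event_date = D0 + days,
    code = rep_len(code, n),
    code_system = rep_len("READ2", n),
    category = rep_len(category, n),
    stringsAsFactors = FALSE
  )
}

dx_bind <- rx_bind

no_rx <- function() rx(numeric(0), character(0))
no_dx <- function() dx(numeric(0), character(0), character(0))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
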