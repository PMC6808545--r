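# Desk-scale simulation settings shared across tests: small libraries
# with enough spiked sequences (>= min_peak_support) to form a
# detectable near-100% peak.
small_sim <- function(seed = 1, ...) {
  simulate_contamination(sim_config(n_transcripts = 200,
                                    length_range = c(300, 800),
                                    seed = seed, ...))
}

# A tiny hit table assembled by hand.
manual_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  names(df) <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")[seq_along(df)]
  df
}

hit <- function(query_id, subject_id, pct_identity, aln_length = 500,
                evalue = 1e-50, bitscore = 900) {
  list(query_id = query_id, subject_id = subject_id,
       pct_identity = pct_identity, aln_length = aln_length,
       mismatches = 0, gap_opens = 0, q_start = 1, q_end = aln_length,
       s_start = 1, s_end = aln_length, evalue = evalue,
       bitscore = bitscore)
}

sample_table <- function(codes, families,
                         clades = rep("Simulatae", length(codes))) {
  data.frame(code = codes,
             species = paste("Species", tolower(codes)),
             family = families, clade = clades,
             stringsAsFactors = FALSE)
}
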