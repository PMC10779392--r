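# Shared fixture builders: everything is generated in code, no stored data.

# A minimal coarse-style region table: n regions per hemisphere.
toy_region_table <- function(n_per_hemi = 2L) {
  n <- 2L * n_per_hemi
  data.frame(label = seq_len(n),
             region = paste0("r", seq_len(n)),
             hemisphere = rep(c("left", "right"), each = n_per_hemi),
             macro_region = rep(paste0("m", seq_len(n_per_hemi)), 2L),
             scale = "coarse", ventricle = FALSE,
             stringsAsFactors = FALSE)
}

# A connectome object wrapped around a given symmetric matrix.
toy_connectome <- function(m, subject = "s1", group = "control") {
  diag(m) <- 1
  structure(list(matrix = m,
                 region_ids = as.character(seq_len(nrow(m))),
                 subject = subject, group = group),
            class = "connectome")
}

# Connectomes whose edge vectors are exactly the given columns.
connectomes_from_edges <- function(edge_matrix, groups) {
  n_edges <- nrow(edge_matrix)
  R <- (1 + sqrt(1 + 8 * n_edges)) / 2
  stopifnot(R == round(R))
  lapply(seq_len(ncol(edge_matrix)), function(s)
    toy_connectome(devectorize_edges(edge_matrix[, s], R),
                   subject = sprintf("s%02d", s), group = groups[s]))
}
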