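## Small fixture builders shared across test files; everything is generated
## in code under fixed seeds.

## long frequency table from a sites x hosts matrix (rows = hosts)
freq_table <- function(f_mat, site_ids = NULL, host_ids = NULL, D = 100L) {
  M <- nrow(f_mat); S <- ncol(f_mat)
  site_ids <- site_ids %||% sprintf("s%03d", seq_len(S))
  host_ids <- host_ids %||% sprintf("h%03d", seq_len(M))
  data.frame(site_id = rep(site_ids, each = M),
             host_id = rep(host_ids, times = S),
             f = as.vector(f_mat),
             D = D, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## tiny well-formed count table
tiny_counts <- function() {
  data.frame(site_id = c("s1", "s1", "s2", "s2"),
             gene_id = "g1",
             site_class = c("synonymous", "synonymous",
                            "nonsynonymous", "nonsynonymous"),
             host_id = c("h1", "h2", "h1", "h2"),
             A = c(12L, 0L, 30L, 15L),
             D = c(40L, 25L, 60L, 30L),
             stringsAsFactors = FALSE)
}

## small mixed-site cohort used by several analysis tests
small_mixed_cohort <- function(seed = 3L) {
  suppressWarnings(generate_cohort(
    cohort_spec(M = 120L, S_strain = 400L, S_evo = 150L, seed = seed)))
}
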