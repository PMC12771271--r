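# Shared fixture builders: everything is generated in code at test time.

tiny_variants <- function() {
  data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    chrom = c("1", "1", "2", "2"),
    pos = c(100L, 400L, 50L, 90L),
    p = c(0.5, 0.01, 0.2, 0.9),
    af = c(0.10, 0.30, 0.25, 0.45),
    stringsAsFactors = FALSE)
}

tiny_sets <- function() {
  data.frame(set_id = c("A", "B"), p = c(0.04, 0.001),
             stringsAsFactors = FALSE)
}

tiny_membership <- function() list(A = c("v1", "v2"), B = c("v3", "v4"))

write_tmp_tsv <- function(df, ..., sep = "\t", ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# independent mean/min/max summation oracle (naive loops, no vectorised reuse)
oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}
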