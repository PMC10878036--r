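# Shared fixtures, built in code.

# tiny counts table
tiny_counts <- function(values = matrix(c(10L, 30L, 5L, 0L), 2, 2,
                                        dimnames = list(c("f1", "f2"),
                                                        c("s1", "s2")))) {
  feature_table(values, "counts")
}

random_counts <- function(nf = 6, ns = 4, max_count = 50) {
  m <- matrix(sample.int(max_count + 1L, nf * ns, replace = TRUE) - 1L, nf, ns,
              dimnames = list(sprintf("f%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  feature_table(m, "counts")
}

# two-layer metadata over `n` months with given temperatures
make_meta <- function(t_surface, t_deep, start_year = 2018L) {
  n <- length(t_surface)
  idx <- seq_len(n) - 1L
  df <- rbind(
    data.frame(sample_id = sprintf("m%02d_surface", idx), month_index = idx,
               layer = "surface", temperature_C = t_surface),
    data.frame(sample_id = sprintf("m%02d_deep", idx), month_index = idx,
               layer = "deep", temperature_C = t_deep))
  validate_metadata(as_metadata(df, start_year))
}

# cached default simulations (built once per test run)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 1L, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_lake(sim_config(seed = seed, ...))
  .sim_cache[[key]]
}
cached_pipeline <- function(seed = 1L) {
  key <- paste0("pl", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- suppressMessages(run_lake_pipeline_sim(cached_sim(seed)))
  .sim_cache[[key]]
}

# brute-force oracles, independent of the implementation paths
bc_brute <- function(x, y) sum(abs(x - y)) / sum(x + y)
shannon_brute <- function(x) {
  p <- x / sum(x); p <- p[p > 0]
  -sum(p * log(p))
}
pearson_brute <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
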