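# shared fixtures and independent oracles

options(hacoef.verbose = FALSE)

# single-boundary decomposition with round numbers: curve (40/30)(70/x - 1),
# bottom/observed/top right-subset sums 10, 25, 40
fix1 <- list(g1 = 40, g2 = 30, y = 70, btm = 10, r1 = 25)

# a 7-member dataset that realizes fix1 exactly from real observations
fix1_obs <- c(4, 6, 6, 7, 7, 18, 22)
fix1_cats <- c("A", "A", "A", "B", "A", "B", "A")

# independent quadrature oracle for the area under the distance curve:
# adaptive integration of the curve itself, no antiderivative involved
quad_area <- function(d, lower, upper, rel.tol = 1e-10) {
  stats::integrate(function(x) (d$g1 / d$g2) * (d$y / x - 1),
                   lower, upper, rel.tol = rel.tol)$value
}

# random valid instance: positive observations, 2..max_n categories, all
# categories nonempty, untied means (regenerated until stratification is ok)
random_instance <- function(max_n = 6, max_size = 50) {
  repeat {
    n <- sample(2:max_n, 1)
    size <- sample(max(n + 1, 5):max_size, 1)
    obs <- round(stats::runif(size, 0.1, 100), 3)
    cats <- sample(letters[seq_len(n)], size, replace = TRUE)
    if (length(unique(cats)) < n) next
    if (stratify(obs, cats)$status == "ok") return(list(obs = obs, cats = cats))
  }
}

# scalar-path HA recomputed boundary by boundary (reference for the
# vectorized engine)
ha_scalar <- function(obs, cats) ha_coefficient(obs, cats)$ha_geometric

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
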