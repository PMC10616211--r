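# Shared fixtures. The standard toy tetramer is expensive to generate
# (its ground truth is a multi-start packing optimisation), so it is built
# once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

std_toy <- function() {
  if (is.null(.fixtures$toy)) .fixtures$toy <- make_toy_tetramer()
  .fixtures$toy
}

std_links <- function() {
  if (is.null(.fixtures$links))
    .fixtures$links <- plant_crosslinks(std_toy())
  .fixtures$links
}

std_assembly_map <- function() list(REC = c("A", "B"), LIG = c("C", "D"))

std_uirs <- function() {
  if (is.null(.fixtures$uirs))
    .fixtures$uirs <- uirs_from_crosslinks(std_links(), std_assembly_map())
  .fixtures$uirs
}

# brute-force oracle: minimum / maximum cross-pair distance by double loop
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}
brute_max_dist <- function(a, b) {
  best <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- max(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

random_rigid <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  list(R = tetherdock:::quat_to_rot(q), t = rnorm(3) * 10)
}

write_mini_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}
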