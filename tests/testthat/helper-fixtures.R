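# Shared fixtures and independent oracles. The oracles deliberately avoid the
# package's own code paths (and R's cor/lm shortcuts where they are the thing
# under test).

tiny_connectome <- function() {
  nn <- neurons_tbl(
    id = c("A", "B", "C"),
    cell_type = c("PRC", "IN1", "prototroch"),
    side = c("left", "right", "left"),
    func_class = c("sensory", "interneuron", "effector")
  )
  lk <- tibble::tibble(pre_id = c("A", "B"), post_id = c("B", "C"),
                       count = c(5L, 2L))
  connectome(nn, lk, individual_id = "tiny")
}

# random connectome over n neurons with random types/sides and a random
# sparse integer edge set
random_connectome <- function(n = 12, seed = 1, n_types = 4, p_edge = 0.3,
                              max_count = 9) {
  withr::with_seed(seed, {
    nn <- neurons_tbl(
      id = sprintf("n%02d", seq_len(n)),
      cell_type = sample(LETTERS[seq_len(n_types)], n, replace = TRUE),
      side = sample(c("left", "right"), n, replace = TRUE),
      func_class = sample(c("sensory", "interneuron", "motoneuron"), n,
                          replace = TRUE)
    )
    pairs <- expand.grid(pre_id = nn$id, post_id = nn$id,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$pre_id != pairs$post_id, ]
    keep <- runif(nrow(pairs)) < p_edge
    lk <- pairs[keep, ]
    lk$count <- sample.int(max_count, sum(keep), replace = TRUE)
    connectome(nn, lk, individual_id = sprintf("rand-%d", seed))
  })
}

# midranks computed by explicit sorting/averaging, no call to rank()
oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2
  }
  r
}

# Pearson correlation from its definition (explicit sums)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midranks(x), oracle_midranks(y))
}

# OLS via the normal equations, solved explicitly
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

write_connectome_csvs <- function(neurons, links, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  np <- file.path(dir, "neurons.csv")
  ep <- file.path(dir, "edges.csv")
  readr::write_csv(neurons, np)
  readr::write_csv(links, ep)
  list(neurons = np, edges = ep, dir = dir)
}
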