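# Independent oracles and small fixture builders shared across tests.

# Brute-force Mann-Kendall S: explicit double loop over pairs.
brute_mk_s <- function(x) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- x[j] - x[i]
      s <- s + (d > 0) - (d < 0)
    }
  }
  s
}

# Brute-force tie-corrected Var(S), counting tie groups by enumeration.
brute_mk_var <- function(x) {
  n <- length(x)
  tie_term <- 0
  for (v in unique(x)) {
    t_g <- sum(x == v)
    if (t_g > 1) tie_term <- tie_term + t_g * (t_g - 1) * (2 * t_g + 5)
  }
  (n * (n - 1) * (2 * n + 5) - tie_term) / 18
}

# Brute-force minimum-cost assignment by permutation enumeration.
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- gtools_permutations(n)
  best <- NULL
  best_cost <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) {
      best_cost <- cst
      best <- p
    }
  }
  list(perm = best, cost = best_cost)
}

# All permutations of 1..n (recursive; n <= 6 in tests).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# A small in-memory record table with controllable fields.
make_records <- function(n = 5,
                         abstract = rep("the virus spread in the city", n),
                         dates = as.Date("2020-02-01") + seq_len(n) - 1,
                         language_tag = rep("en", n)) {
  tibble::tibble(
    doc_id = sprintf("r%03d", seq_len(n)),
    title = NA_character_,
    abstract = abstract,
    pub_date = dates,
    language_tag = language_tag
  )
}

default_test_period <- function() {
  study_period("2020-01-24", "2020-04-02", "2019-12-12")
}

# Block-diagonal term matrix with `blocks` disjoint term groups; documents
# in block g use only block g's terms.
block_matrix <- function(blocks = 3, docs_per_block = 5, terms_per_block = 4,
                         seed = 1) {
  set.seed(seed)
  n <- blocks * docs_per_block
  m <- blocks * terms_per_block
  R <- matrix(0, n, m)
  for (g in seq_len(blocks)) {
    rows <- (g - 1) * docs_per_block + seq_len(docs_per_block)
    cols <- (g - 1) * terms_per_block + seq_len(terms_per_block)
    R[rows, cols] <- matrix(stats::runif(length(rows) * length(cols), 1, 3),
                            length(rows))
  }
  rownames(R) <- sprintf("d%03d", seq_len(n))
  colnames(R) <- sprintf("t%03d", seq_len(m))
  R
}
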