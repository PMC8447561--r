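# Independent oracle implementations used to cross-check the package's
# algorithms. These deliberately use naive formulations (full re-scan,
# explicit pair counting, exhaustive enumeration) and share no code with
# the implementations they check.

# Naive O(n^3) re-scan Ward agglomerator: at every step the distance
# between two clusters is recomputed from scratch from the original
# dissimilarities via the generalized Ward form
#   d(A,B)^2 = 2 nA nB/(nA+nB) * (S_AB/(nA nB) - T_A/nA^2 - T_B/nB^2)
# with S_AB the sum of squared cross dissimilarities and T_A the sum of
# squared within dissimilarities over unordered pairs. Ties are broken
# by the lowest smaller creation index, then the lowest larger one
# (matching the documented convention).
oracleWard <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)  # member sets, creation order
  active <- seq_len(n)
  heights <- numeric(n - 1)
  members <- vector("list", n - 1)
  d2 <- d^2
  cdist <- function(A, B) {
    nA <- length(A); nB <- length(B)
    S <- sum(d2[A, B])
    TA <- sum(d2[A, A]) / 2
    TB <- sum(d2[B, B]) / 2
    sqrt(max(2 * nA * nB / (nA + nB) *
               (S / (nA * nB) - TA / nA^2 - TB / nB^2), 0))
  }
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_along(active)[-length(active)]) {
      for (j in seq((i + 1), length(active))) {
        v <- cdist(clusters[[active[i]]], clusters[[active[j]]])
        if (is.null(best) || v < best$v) best <- list(v = v, i = i, j = j)
      }
    }
    heights[s] <- best$v
    merged <- sort(c(clusters[[active[best$i]]], clusters[[active[best$j]]]))
    members[[s]] <- merged
    clusters[[n + s]] <- merged
    active <- c(active[-c(best$i, best$j)], n + s)
  }
  list(heights = heights, members = members)
}

# member sets per merge of a LinkageTree, sorted, for comparison
treeMembers <- function(tree) {
  m <- tree@merge
  out <- vector("list", nrow(m))
  get <- function(k) if (k < 0) -k else out[[k]]
  for (s in seq_len(nrow(m)))
    out[[s]] <- sort(c(get(m[s, 1]), get(m[s, 2])))
  out
}

# Brute-force Mann-Whitney AUC: explicit loop over all positive-negative
# pairs, ties counted one half.
bruteAuc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive exact two-sided Wilcoxon rank-sum p-value: enumerate all
# C(n1+n2, n1) assignments of the pooled ranks to group 1 and double the
# attained tail (capped at 1), the standard exact two-sided convention.
enumWilcoxP <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  pooled <- c(x1, x2)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  half <- n1 * n2 / 2
  p <- if (w_obs > half) mean(ws >= w_obs) else mean(ws <= w_obs)
  min(2 * p, 1)
}

# small complete test cohort built in code
toyCohort <- function(values, categories = "lipid", id = "toy",
                      patientData = NULL) {
  schema <- featureSchema(rownames(values), categories)
  SepsisCohort(values, schema, patientData, cohortId = id)
}

# shorthand: planted-condition derivation config (whole phenotype
# contrast scaled so the weakest lipoprotein reaches 2 SD)
plantedConfig <- function(n = 200, missingRate = 0.05) {
  cfg <- defaultDerivationConfig(n = n, missingRate = missingRate)
  fac <- max(2 / phenotypeSeparation(cfg)[lipoproteinPanel()])
  scaleSeparation(cfg, fac)
}
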