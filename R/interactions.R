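#' Cell-cell interaction statistics with a permutation null
#'
#' For every unordered pair of immune subpopulations (including
#' within-type pairs A-A, counted once per unordered cell pair) computes:
#' the contact count on the contact graph; the "(p)-normalized
#' interaction" = pair contacts / total immune contacts (these sum to 1
#' over all unordered pairs); the "normalized interaction" = pair
#' contacts / (n_A + n_B) (n_A for A-A); and an enrichment test against
#' random background interactions, obtained by permuting subpopulation
#' labels across the immune-cell positions with the geometry (and hence
#' the total random contact rate) held fixed. Tumor and endothelial cells
#' are excluded from all totals.
#'
#' The permutation p-value is (1 + #\{null >= observed\}) / (1 + nPerm),
#' one-sided for enrichment; z = (obs - null mean) / null sd. Pairs whose
#' denominator is zero are flagged `excluded` (no value) rather than
#' propagating NaN.
#'
#' @param graph A [ContactGraph-class].
#' @param assignment Output of [assignPhenotypes()] over the same cells.
#' @param nPerm Number of label permutations (>= 1; default 1000).
#' @param seed Optional RNG seed for the permutations.
#' @param immuneLineages Lineages whose cells enter the analysis.
#' @param areaMM2 Optional area for the descriptive contacts-per-area
#'   rate (attached as attribute `contactsPerMM2`).
#' @return data.frame with one row per unordered subpopulation pair:
#'   subpop_a, subpop_b, n_a, n_b, contacts, p_normalized, normalized,
#'   null_mean, null_sd, z, p_perm, excluded. Attributes: totalContacts,
#'   nImmune, contactsPerMM2.
#' @export
interactionStatistics <- function(graph, assignment, nPerm = 1000,
                                  seed = NULL,
                                  immuneLineages = c("CYTOTOXIC_T",
                                                     "HELPER_T", "OTHER_T",
                                                     "DC", "NK"),
                                  areaMM2 = NA_real_) {
  stopifnot(is(graph, "ContactGraph"))
  if (nrow(assignment) != length(graph@cellId) ||
      !all(assignment$cell_id == graph@cellId))
    stop("graph and assignment must cover the same cells in the same order")
  if (!is.numeric(nPerm) || nPerm < 1) stop("nPerm must be >= 1")
  nPerm <- as.integer(nPerm)
  if (!is.null(seed)) set.seed(seed)

  imm <- which(as.character(assignment$lineage) %in% immuneLineages)
  lab <- factor(as.character(assignment$subpopulation[imm]))
  k <- nlevels(lab)
  if (k < 2L)
    warning("fewer than two immune subpopulations present: ",
            "the permutation null is degenerate")
  code <- as.integer(lab)
  nPer <- tabulate(code, nbins = k)

  ## immune-immune edges, re-indexed into the immune subset
  map <- integer(length(graph@cellId)); map[imm] <- seq_along(imm)
  keep <- graph@edgeI %in% imm & graph@edgeJ %in% imm
  ei <- map[graph@edgeI[keep]]; ej <- map[graph@edgeJ[keep]]
  total <- length(ei)

  ## unordered pair bookkeeping
  pairA <- rep(seq_len(k), times = k - seq_len(k) + 1L)
  pairB <- unlist(lapply(seq_len(k), function(a) a:k), use.names = FALSE)
  nPairs <- length(pairA)
  pairIndex <- matrix(0L, k, k)
  pairIndex[cbind(pairA, pairB)] <- seq_len(nPairs)
  pairIndex[cbind(pairB, pairA)] <- seq_len(nPairs)

  countPairs <- function(codes) {
    a <- codes[ei]; b <- codes[ej]
    tabulate(pairIndex[cbind(pmin(a, b), pmax(a, b))], nbins = nPairs)
  }

  obs <- countPairs(code)
  denom <- ifelse(pairA == pairB, nPer[pairA], nPer[pairA] + nPer[pairB])
  obsNorm <- ifelse(denom > 0, obs / denom, NA_real_)

  geCount <- integer(nPairs)
  s1 <- numeric(nPairs); s2 <- numeric(nPairs)
  nImm <- length(imm)
  for (p in seq_len(nPerm)) {
    perm <- code[sample.int(nImm)]
    cnt <- countPairs(perm)
    geCount <- geCount + (cnt >= obs)
    s1 <- s1 + cnt; s2 <- s2 + cnt * cnt
  }
  nullMeanCnt <- s1 / nPerm
  nullVarCnt <- pmax(s2 / nPerm - nullMeanCnt^2, 0)
  nullSdCnt <- sqrt(nullVarCnt * nPerm / max(nPerm - 1L, 1L))

  excluded <- denom == 0L | total == 0L
  res <- data.frame(subpop_a = levels(lab)[pairA],
                    subpop_b = levels(lab)[pairB],
                    n_a = nPer[pairA], n_b = nPer[pairB],
                    contacts = obs,
                    p_normalized = if (total > 0) obs / total else NA_real_,
                    normalized = obsNorm,
                    null_mean = ifelse(denom > 0, nullMeanCnt / denom, NA_real_),
                    null_sd = ifelse(denom > 0, nullSdCnt / denom, NA_real_),
                    z = ifelse(denom > 0 & nullSdCnt > 0,
                               (obs - nullMeanCnt) / nullSdCnt, NA_real_),
                    p_perm = ifelse(denom > 0,
                                    (1 + geCount) / (1 + nPerm), NA_real_),
                    excluded = excluded,
                    stringsAsFactors = FALSE)
  attr(res, "totalContacts") <- total
  attr(res, "nImmune") <- nImm
  attr(res, "contactsPerMM2") <- if (is.na(areaMM2)) NA_real_ else total / areaMM2
  res
}

#' Extract one pair's statistic from an interaction table
#'
#' @param result Output of [interactionStatistics()].
#' @param a,b Subpopulation labels (order irrelevant).
#' @param what Column to extract.
#' @return The requested scalar, or NA when the pair is absent.
#' @export
interactionValue <- function(result, a, b, what = "p_perm") {
  hit <- (result$subpop_a == a & result$subpop_b == b) |
         (result$subpop_a == b & result$subpop_b == a)
  if (!any(hit)) return(NA_real_)
  result[[what]][which(hit)[1]]
}
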