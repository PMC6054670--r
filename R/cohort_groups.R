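# Recurrent-LoH pattern mining, three-group tumor classification, and exact
# tests of clinical association.

#' Mine the recurrent whole-chromosome LoH set
#'
#' High-LoH tumors are those with LoH of at least \code{high_loh_min}
#' chromosomes; the recurrent set is the chromosomes with LoH in at least
#' \code{member_freq} of the high-LoH tumors. With no high-LoH tumors the
#' set is empty (not an error).
#'
#' @param karyotypes List of \code{karyotype} objects (>= 2).
#' @param high_loh_min LoH-chromosome count defining a high-LoH tumor
#'   (default 8).
#' @param member_freq Membership frequency threshold (default 0.8).
#' @return List of class \code{recurrent_set}: \code{chromosomes},
#'   \code{support} (number of tumors with LoH of every member),
#'   \code{member_freq} (per-chromosome frequency among high-LoH tumors),
#'   \code{n_high_loh}.
#' @export
mine_recurrent_loh <- function(karyotypes, high_loh_min = 8,
                               member_freq = 0.8) {
  stopifnot(length(karyotypes) >= 2)
  n_loh <- vapply(karyotypes, `[[`, integer(1), "n_loh")
  high <- karyotypes[n_loh >= high_loh_min]
  if (!length(high)) {
    return(structure(list(chromosomes = character(0), support = 0L,
                          member_freq = numeric(0), n_high_loh = 0L),
                     class = "recurrent_set"))
  }
  loh_mat <- sapply(high, function(k) k$calls$loh %in% TRUE)
  rownames(loh_mat) <- high[[1]]$calls$chrom
  freq <- rowMeans(loh_mat)
  members <- names(freq)[freq >= member_freq]
  support <- if (length(members)) {
    sum(apply(loh_mat[members, , drop = FALSE], 2, all))
  } else 0L
  structure(list(chromosomes = members, support = as.integer(support),
                 member_freq = freq[members],
                 n_high_loh = length(high)),
            class = "recurrent_set")
}

#' Classify tumors into the three karyotype groups
#'
#' Group 3: no somatic MEN1 mutation. Among MEN1-mutant tumors, Group 1:
#' chromosome 11 LoH and LoH overlapping at least \code{min_overlap} of the
#' recurrent set's members; Group 2: the rest (MEN1-mutant without the
#' recurrent pattern). MEN1-mutant tumors lacking chromosome 11 LoH are
#' assigned Group 2 and flagged as anomalies.
#'
#' @param karyotypes List of \code{karyotype} objects.
#' @param men1_status Named logical vector (somatic MEN1 mutation per
#'   tumor), names = tumor ids.
#' @param recurrent_set A \code{recurrent_set} (or character vector of
#'   chromosomes).
#' @param min_overlap Minimum fraction of recurrent-set members with LoH for
#'   Group 1 (default 0.8).
#' @return data.frame with tumor_id, group, men1, chr11_loh, n_loh,
#'   recurrent_overlap, anomaly.
#' @export
classify_groups <- function(karyotypes, men1_status, recurrent_set,
                            min_overlap = 0.8) {
  set <- if (inherits(recurrent_set, "recurrent_set")) {
    recurrent_set$chromosomes
  } else as.character(recurrent_set)
  rows <- lapply(karyotypes, function(k) {
    id <- k$tumor_id
    if (!id %in% names(men1_status) || is.na(men1_status[[id]])) {
      stop("missing MEN1 status for tumor ", id)
    }
    men1 <- men1_status[[id]]
    loh_ch <- k$calls$chrom[k$calls$loh %in% TRUE]
    chr11 <- "chr11" %in% loh_ch
    overlap <- if (length(set)) mean(set %in% loh_ch) else 0
    group <- if (!men1) 3L
    else if (chr11 && length(set) && overlap >= min_overlap) 1L
    else 2L
    data.frame(tumor_id = id, group = group, men1 = men1, chr11_loh = chr11,
               n_loh = k$n_loh, recurrent_overlap = overlap,
               anomaly = men1 && !chr11, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test for 2xk tables (k = 2 or 3)
#'
#' Exact conditional test with both margins fixed: the p-value is the sum of
#' multivariate hypergeometric probabilities of all tables whose probability
#' does not exceed that of the observed table (the probability-mass
#' two-sided convention).
#'
#' @param tab 2x2 or 2x3 matrix of non-negative counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2xk <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2 || !ncol(tab) %in% 2:3) stop("need a 2x2 or 2x3 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  cs <- colSums(tab)
  rs <- rowSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("row and column sums must be > 0")
  n <- sum(tab)
  r1 <- rs[1]
  # P(top row = x | margins) = prod_j C(c_j, x_j) / C(n, r1)
  log_denom <- lchoose(n, r1)
  tab_logp <- function(x) sum(lchoose(cs, x)) - log_denom
  obs <- tab_logp(tab[1, ])
  total <- 0
  k <- ncol(tab)
  x1_max <- min(cs[1], r1)
  for (x1 in 0:x1_max) {
    if (k == 2) {
      x2 <- r1 - x1
      if (x2 < 0 || x2 > cs[2]) next
      lp <- tab_logp(c(x1, x2))
      if (lp <= obs + 1e-7) total <- total + exp(lp)
    } else {
      for (x2 in 0:min(cs[2], r1 - x1)) {
        x3 <- r1 - x1 - x2
        if (x3 < 0 || x3 > cs[3]) next
        lp <- tab_logp(c(x1, x2, x3))
        if (lp <= obs + 1e-7) total <- total + exp(lp)
      }
    }
  }
  min(total, 1)
}

#' Test association of group membership with clinical features
#'
#' Builds group-by-grade and group-by-metastasis contingency tables and
#' applies [fisher_exact_2xk()] with the binary split "Group 1 vs rest" on
#' the group axis (grade collapsed to low = G1 vs higher when it has three
#' levels would lose information, so grade enters as its observed levels, up
#' to 3). Tumors missing clinical fields are excluded with a warning.
#'
#' @param groups data.frame from [classify_groups()].
#' @param clinical data.frame with tumor_id, grade, metastasis.
#' @return List with \code{grade} and \code{metastasis} elements, each
#'   containing the contingency table and p-value (or NULL with a warning
#'   when degenerate).
#' @export
associate_clinical <- function(groups, clinical) {
  m <- merge(groups, clinical[, c("tumor_id", "grade", "metastasis")],
             by = "tumor_id")
  miss <- is.na(m$grade) | is.na(m$metastasis)
  if (any(miss)) {
    warning(sum(miss), " tumor(s) missing clinical fields excluded")
    m <- m[!miss, , drop = FALSE]
  }
  g1 <- factor(ifelse(m$group == 1, "group1", "other"),
               levels = c("group1", "other"))
  one_test <- function(fac) {
    tab <- table(g1, fac)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || !ncol(tab) %in% 2:3 || any(rowSums(tab) == 0)) {
      warning("degenerate contingency table; association skipped")
      return(list(table = tab, p = NA_real_))
    }
    list(table = tab, p = fisher_exact_2xk(unclass(tab)))
  }
  grade_fac <- factor(m$grade)
  if (nlevels(grade_fac) > 3) {
    grade_fac <- factor(ifelse(m$grade == levels(grade_fac)[1],
                               levels(grade_fac)[1], "higher"))
  }
  list(grade = one_test(grade_fac),
       metastasis = one_test(factor(m$metastasis,
                                    levels = c(FALSE, TRUE),
                                    labels = c("no_met", "met"))))
}
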