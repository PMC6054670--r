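#' Expected tumor B-allele frequency under the purity mixture model
#'
#' A sequenced tumor sample is a mixture of tumor cells (fraction
#' \code{purity}) carrying \code{total_cn} copies of the locus, of which
#' \code{alt_copies} carry the ALT allele, and diploid stromal cells carrying
#' one ALT and one REF copy (the site is germline heterozygous). The expected
#' ALT read fraction is the ALT copy mass over the total copy mass:
#' \deqn{b = \frac{\rho a + (1-\rho)}{\rho c + 2(1-\rho)}}
#'
#' @param purity Tumor cell fraction \eqn{\rho}, in (0, 1].
#' @param total_cn Integer total copy number \eqn{c \ge 0} in tumor cells.
#' @param alt_copies Number of ALT-bearing copies \eqn{a}, with
#'   \eqn{0 \le a \le c}.
#' @return Expected tumor BAF in [0, 1]. Vectorized over all arguments.
#' @examples
#' expected_baf(1, 1, 1)        # hemizygous ALT in pure tumor -> 1
#' expected_baf(0.5, 1, 1)      # one-copy loss, ALT retained -> 2/3
#' expected_baf(0.5, 2, 2)      # copy-neutral LoH -> 0.75
#' @export
expected_baf <- function(purity, total_cn, alt_copies) {
  n <- max(length(purity), length(total_cn), length(alt_copies))
  purity <- rep_len(purity, n)
  total_cn <- rep_len(total_cn, n)
  alt_copies <- rep_len(alt_copies, n)
  if (any(purity <= 0 | purity > 1)) {
    stop("purity must be in (0, 1]")
  }
  if (any(total_cn < 0) || any(alt_copies < 0) || any(alt_copies > total_cn)) {
    stop("need 0 <= alt_copies <= total_cn")
  }
  if (any(purity == 1 & total_cn == 0)) {
    stop("purity = 1 with total_cn = 0 leaves no DNA; BAF undefined")
  }
  (purity * alt_copies + (1 - purity)) / (purity * total_cn + 2 * (1 - purity))
}

#' Expected tumor/normal log2 coverage ratio under the purity mixture model
#'
#' Relative to a diploid normal, a segment at integer copy number \code{cn} in
#' a tumor of purity \eqn{\rho} has expected coverage ratio
#' \eqn{(\rho c + 2(1-\rho))/2}, hence expected log2 ratio
#' \eqn{\log_2((\rho c + 2(1-\rho))/2)}.
#'
#' @inheritParams expected_baf
#' @param cn Integer copy number \eqn{c \ge 0}.
#' @param eps Floor applied to the ratio before taking log2, so that
#'   \code{cn = 0} at purity 1 yields a large negative value rather than
#'   \code{-Inf}.
#' @return Expected log2 ratio; vectorized.
#' @export
expected_log_ratio <- function(purity, cn, eps = 1e-6) {
  if (any(purity <= 0 | purity > 1)) {
    stop("purity must be in (0, 1]")
  }
  if (any(cn < 0)) {
    stop("cn must be >= 0")
  }
  log2(pmax(purity * cn + 2 * (1 - purity), eps) / 2)
}
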