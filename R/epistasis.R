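# Epistasis models over deep mutational scanning fitness tables and their
# correlation with covariation scores. Fitness is on the wild-type = 1
# scale throughout; epsilon is the deviation of the double mutant from the
# null combination of the two singles.

#' Epistasis score of one double mutant under a null model
#'
#' Given single-mutant fitness values \code{m_a}, \code{m_b} and the double
#' mutant \code{m_ab} (wild type normalized to \code{wt} = 1), the deviation
#' from each null model is:
#' \itemize{
#'   \item product: \code{m_ab - m_a * m_b}
#'   \item additive: \code{(m_ab + wt) - (m_a + m_b)}
#'   \item log: \code{m_ab - log2((2^m_a - wt) * (2^m_b - wt) + wt)}
#'   \item min: \code{m_ab - min(m_a, m_b)}
#' }
#'
#' @param m_a,m_b,m_ab Fitness values (vectorized).
#' @param model One of \code{"product"}, \code{"additive"}, \code{"log"},
#'   \code{"min"}.
#' @param wt Wild-type fitness (1 by convention).
#' @return Epsilon values; under the log model, records whose log2 argument
#'   is not positive yield \code{NA} (callers count and skip them).
#' @export
epistasis_score <- function(m_a, m_b, m_ab,
                            model = c("product", "additive", "log", "min"),
                            wt = 1) {
  model <- match.arg(model)
  switch(model,
    product = m_ab - m_a * m_b,
    additive = (m_ab + wt) - (m_a + m_b),
    log = {
      arg <- (2^m_a - wt) * (2^m_b - wt) + wt
      out <- rep_len(NA_real_, length(arg))
      ok <- arg > 0
      out[ok] <- rep_len(m_ab, length(arg))[ok] - log2(arg[ok])
      out
    },
    min = m_ab - pmin(m_a, m_b)
  )
}

#' Transform raw screen scores onto the wild-type = 1 fitness scale
#'
#' Deep mutational scans report fitness on different scales; two common
#' log-scale conventions are handled: \code{exp_lnW} exponentiates log
#' fitness (lnW, where wild type is 0), and \code{exp_toxicity_normalized}
#' exponentiates and then divides by the transformed wild-type value so
#' the wild type lands at 1.
#'
#' @param values Numeric vector of raw scores.
#' @param transform \code{"none"}, \code{"exp_lnW"}, or
#'   \code{"exp_toxicity_normalized"}.
#' @param wt_value Raw wild-type score, required for the normalized
#'   transform.
#' @param base Base of the exponential transform (\code{exp(1)} for
#'   natural-log scores; a config knob because source studies differ).
#' @return Transformed fitness values.
#' @export
preprocess_fitness <- function(values,
                               transform = c("none", "exp_lnW",
                                             "exp_toxicity_normalized"),
                               wt_value = NULL, base = exp(1)) {
  transform <- match.arg(transform)
  switch(transform,
    none = values,
    exp_lnW = base^values,
    exp_toxicity_normalized = {
      if (is.null(wt_value))
        stop("wt_value is required for exp_toxicity_normalized")
      base^values / base^wt_value
    }
  )
}

#' Aggregate double-mutant records into per-pair epistasis values
#'
#' For every residue pair, the signed epsilon of all substitution
#' combinations is averaged and the absolute value of that mean taken
#' (mean first, absolute value second): the result is the average
#' displacement from wild-type behavior, directionless like the covariation
#' scores it is compared to. Records with an invalid log-model argument are
#' skipped for that model only.
#'
#' @param records Data frame with columns \code{pos_a}, \code{pos_b},
#'   \code{m_a}, \code{m_b}, \code{m_ab} (wild-type = 1 scale).
#' @param model Epistasis model passed to \code{\link{epistasis_score}}.
#' @param wt Wild-type fitness.
#' @return Data frame with \code{pos_i < pos_j}, \code{epsilon} (absolute
#'   mean), and \code{n_records}; attribute \code{n_skipped} counts dropped
#'   log-model records.
#' @export
pair_epistasis <- function(records, model, wt = 1) {
  need <- c("pos_a", "pos_b", "m_a", "m_b", "m_ab")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (any(records$pos_a == records$pos_b))
    stop("double mutant with both mutations at the same position")
  eps <- epistasis_score(records$m_a, records$m_b, records$m_ab, model, wt)
  skipped <- sum(is.na(eps))
  ok <- !is.na(eps)
  pi <- pmin(records$pos_a, records$pos_b)[ok]
  pj <- pmax(records$pos_a, records$pos_b)[ok]
  key <- paste(pi, pj)
  mean_eps <- tapply(eps[ok], key, mean)
  n_rec <- tapply(eps[ok], key, length)
  parts <- do.call(rbind, strsplit(names(mean_eps), " ", fixed = TRUE))
  out <- data.frame(pos_i = as.integer(parts[, 1]),
                    pos_j = as.integer(parts[, 2]),
                    epsilon = abs(as.numeric(mean_eps)),
                    n_records = as.integer(n_rec))
  out <- out[order(out$pos_i, out$pos_j), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  attr(out, "model") <- model
  out
}

#' Correlate covariation scores with per-pair epistasis
#'
#' Pearson correlation between the orientation-adjusted raw covariation
#' score (negated when lower means more coupled, so that higher always
#' means more coupled) and the absolute mean epistasis, over the pairs
#' present in both tables.
#'
#' @param pairs A \code{pair_scores} object.
#' @param ep A per-pair epistasis table from \code{\link{pair_epistasis}}.
#' @return List with \code{r} (Pearson correlation, \code{NA} with a warning
#'   if either side has zero variance), \code{n} (shared pairs), and
#'   \code{model}.
#' @export
correlate_with_covariation <- function(pairs, ep) {
  stopifnot(inherits(pairs, "pair_scores"))
  key_p <- paste(pairs$pos_i, pairs$pos_j)
  key_e <- paste(ep$pos_i, ep$pos_j)
  idx <- match(key_e, key_p)
  ok <- !is.na(idx)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 pairs shared between scores and epistasis")
  sc <- pairs$score[idx[ok]]
  if (attr(pairs, "lower_is_coupled")) sc <- -sc
  ee <- ep$epsilon[ok]
  if (stats::sd(sc) == 0 || stats::sd(ee) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, n = n, model = attr(ep, "model")))
  }
  list(r = stats::cor(sc, ee), n = n, model = attr(ep, "model"))
}

#' Read double- and single-mutant fitness tables
#'
#' Joins a doubles TSV (\code{pos_a}, \code{aa_a}, \code{pos_b},
#' \code{aa_b}, \code{fitness}) with a singles TSV (\code{pos}, \code{aa},
#' \code{fitness}) into the record format \code{\link{pair_epistasis}}
#' consumes. Doubles whose constituent singles are missing are dropped with
#' a warning.
#'
#' @param doubles_path,singles_path TSV file paths.
#' @return Records data frame.
#' @export
read_fitness_tables <- function(doubles_path, singles_path) {
  dbl <- utils::read.table(doubles_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  sgl <- utils::read.table(singles_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  key <- function(p, a) paste(p, a)
  skey <- key(sgl$pos, sgl$aa)
  ma <- sgl$fitness[match(key(dbl$pos_a, dbl$aa_a), skey)]
  mb <- sgl$fitness[match(key(dbl$pos_b, dbl$aa_b), skey)]
  ok <- !is.na(ma) & !is.na(mb)
  if (any(!ok))
    warning(sum(!ok), " double mutants dropped (missing single-mutant fitness)")
  data.frame(pos_a = dbl$pos_a[ok], pos_b = dbl$pos_b[ok],
             m_a = ma[ok], m_b = mb[ok], m_ab = dbl$fitness[ok])
}
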