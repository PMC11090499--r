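# Rank transform of onset timelines and PCA ordination of taxa.

#' Rank the events of one timeline
#'
#' Observed onsets are ranked ascending with average ranks for ties. Under
#' `never_policy = "last"`, never-ossifying events share the tie-averaged
#' rank positioned after all observed events; under `"missing"` they are
#' `NA`. Unknown events are always `NA`.
#'
#' @inheritParams encode_timeline
#' @param tie_policy Only `"average_rank"` is defined.
#' @return Named numeric vector of ranks over the registry events with an
#'   attribute `provenance` (per event: `"observed"`, `"never_last"` or
#'   `NA`).
#' @examples
#' reg <- default_registry()
#' t <- timeline("Psin", c(CBI = 29, CBII = 37, CHp = 41, CHa = 44,
#'                         CHi = 44.5, EPI = "never", PL = "never"), reg)
#' rank_events(t, reg)  # EPI and PL share rank 6.5
#' @export
rank_events <- function(t, registry, never_policy = c("last", "missing"),
                        tie_policy = "average_rank", digits = NULL) {
  never_policy <- match.arg(never_policy)
  tie_policy <- match.arg(tie_policy, "average_rank")
  stopifnot(inherits(t, "ossification_timeline"))
  codes <- registry$codes
  st <- t$status[codes]
  v <- t$onset[codes]
  if (!is.null(digits)) v <- round(v, digits)
  ranks <- setNames(rep(NA_real_, length(codes)), codes)
  prov <- setNames(rep(NA_character_, length(codes)), codes)
  obs <- which(st == "observed")
  if (length(obs)) {
    ranks[obs] <- rank(v[obs], ties.method = "average")
    prov[obs] <- "observed"
  }
  nev <- which(st == "never")
  if (length(nev) && never_policy == "last") {
    m <- length(obs)
    ranks[nev] <- mean(seq(m + 1L, m + length(nev)))
    prov[nev] <- "never_last"
  }
  attr(ranks, "provenance") <- prov
  ranks
}

#' Build a taxa x events rank matrix
#'
#' @param timelines List of [timeline()] objects with unique taxa.
#' @inheritParams rank_events
#' @param impute `"column_mean"` replaces missing cells by the mean of the
#'   observed cells in that event's column (flagged `"imputed"`); `"none"`
#'   leaves them `NA` (downstream PCA will then refuse the matrix).
#' @return Object of class `rank_matrix`: list with `ranks` (numeric taxa
#'   x events matrix), `provenance` (same shape), `taxa`, `events`.
#' @export
build_rank_matrix <- function(timelines, registry,
                              never_policy = c("last", "missing"),
                              tie_policy = "average_rank",
                              impute = c("column_mean", "none"),
                              digits = NULL) {
  never_policy <- match.arg(never_policy)
  impute <- match.arg(impute)
  taxa <- vapply(timelines, function(t) t$taxon, "")
  if (anyDuplicated(taxa))
    stop_arg("duplicate taxa: %s",
             paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  rk <- lapply(timelines, rank_events, registry = registry,
               never_policy = never_policy, tie_policy = tie_policy,
               digits = digits)
  ranks <- do.call(rbind, lapply(rk, as.numeric))
  prov <- do.call(rbind, lapply(rk, function(r) attr(r, "provenance")))
  dimnames(ranks) <- dimnames(prov) <- list(taxa, registry$codes)
  if (impute == "column_mean") {
    for (j in seq_len(ncol(ranks))) {
      nas <- is.na(ranks[, j])
      if (!any(nas)) next
      if (all(nas))
        stop_arg("cannot impute event '%s': no observed cell in its column",
                 registry$codes[j])
      ranks[nas, j] <- mean(ranks[!nas, j])
      prov[nas, j] <- "imputed"
    }
  }
  structure(list(ranks = ranks, provenance = prov, taxa = taxa,
                 events = registry$codes),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("Rank matrix: %d taxa x %d events\n",
              nrow(x$ranks), ncol(x$ranks)))
  print(x$ranks)
  invisible(x)
}

#' PCA ordination of a rank matrix
#'
#' Principal component analysis of the taxa x events rank matrix:
#' column-centered data projected on the eigenvectors of the covariance
#' matrix (ranks share a common scale, so covariance — not correlation —
#' is the default). Eigenvector signs follow a deterministic convention:
#' in each loading column the entry of largest magnitude is positive.
#'
#' @param m A [build_rank_matrix()] result or a plain numeric matrix
#'   (taxa in rows) without missing cells.
#' @param centering `"center_only"` (covariance PCA, default) or
#'   `"correlation"` (unit-variance scaling as well).
#' @return Object of class `ordination_result`: `scores` (taxa x
#'   components), `loadings` (events x components, orthonormal columns),
#'   `explained_variance` (fractions summing to 1), `sdev`.
#' @export
pca_ordination <- function(m, centering = c("center_only", "correlation")) {
  centering <- match.arg(centering)
  x <- if (inherits(m, "rank_matrix")) m$ranks else as.matrix(m)
  if (anyNA(x))
    stop_arg("rank matrix contains missing cells; impute or drop them first")
  if (nrow(x) < 2L) stop_arg("need at least two taxa")
  vars <- apply(x, 2L, stats::var)
  if (all(vars == 0))
    stop_arg("degenerate input: no column varies across taxa")
  if (centering == "correlation" && any(vars == 0))
    stop_arg("correlation PCA undefined with zero-variance columns")
  pc <- stats::prcomp(x, center = TRUE, scale. = centering == "correlation")
  scores <- pc$x
  loadings <- pc$rotation
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev / sum(ev), sdev = pc$sdev,
                 centering = centering),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("PCA ordination:", nrow(x$scores), "taxa,",
      ncol(x$scores), "components\n")
  cat("explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}
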