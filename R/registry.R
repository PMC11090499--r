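# Event registry and per-taxon ossification timelines.

#' Create an event registry
#'
#' An event registry fixes the set of developmental events under study and,
#' crucially, their canonical order: the order defines the column order of
#' every event-pair matrix and rank matrix built from it, so results are
#' reproducible across runs and machines.
#'
#' @param codes Character vector of unique, short event identifiers.
#' @param labels Optional named character vector mapping codes to full names.
#' @return An object of class `event_registry` with elements `codes` and
#'   `labels`.
#' @examples
#' reg <- event_registry(c("a", "b", "c"))
#' default_registry()
#' @export
event_registry <- function(codes, labels = NULL) {
  codes <- as.character(codes)
  if (anyDuplicated(codes))
    stop_arg("event codes must be unique (duplicated: %s)",
             paste(unique(codes[duplicated(codes)]), collapse = ", "))
  if (length(codes) < 1L) stop_arg("registry needs at least one event code")
  if (is.null(labels)) labels <- setNames(codes, codes)
  labels <- labels[codes]
  names(labels) <- codes
  structure(list(codes = codes, labels = labels), class = "event_registry")
}

#' Default hyoid-apparatus event registry
#'
#' The seven skeletal elements of the turtle hyoid apparatus whose onset of
#' ossification is scored: cornu branchiale I and II, the posterior,
#' intermediate and anterior ossification centers of the corpus hyoideus,
#' epibranchial I, and the processus lingualis.
#'
#' @return An `event_registry` of the 7 hyoid elements in canonical order.
#' @export
default_registry <- function() {
  event_registry(
    codes = c("CBI", "CBII", "CHp", "CHi", "CHa", "EPI", "PL"),
    labels = c(CBI = "cornu branchiale I",
               CBII = "cornu branchiale II",
               CHp = "corpus hyoideus, posterior center",
               CHi = "corpus hyoideus, intermediate center",
               CHa = "corpus hyoideus, anterior center",
               EPI = "epibranchial I",
               PL = "processus lingualis"))
}

#' @export
print.event_registry <- function(x, ...) {
  cat("Event registry with", length(x$codes), "events:\n")
  for (cd in x$codes) cat(sprintf("  %-5s %s\n", cd, x$labels[[cd]]))
  invisible(x)
}

#' Create an ossification timeline for one taxon
#'
#' A timeline records, for every event in the registry, either a numeric
#' onset (days of incubation or an ordinal stage), the status `"never"`
#' (the element never ossifies in this taxon), or `"unknown"` (not scored).
#' Events not mentioned in `onsets` are `"unknown"`.
#'
#' @param taxon Taxon name.
#' @param onsets Named vector; values are finite numbers or the strings
#'   `"never"` / `"unknown"`. Names must be registry codes.
#' @param registry An [event_registry()].
#' @return An object of class `ossification_timeline` with fields `taxon`,
#'   `onset` (named numeric, `NA` unless observed) and `status` (named
#'   character in `observed`, `never`, `unknown`, over all registry codes).
#' @examples
#' reg <- default_registry()
#' timeline("Pelodiscus_sinensis",
#'          c(CBI = 29, CBII = 37, CHp = 41, CHa = 44, CHi = 44.5,
#'            EPI = "never", PL = "never"), reg)
#' @export
timeline <- function(taxon, onsets, registry) {
  stopifnot(inherits(registry, "event_registry"))
  ev <- names(onsets)
  if (length(onsets) && (is.null(ev) || any(!nzchar(ev))))
    stop_arg("onsets must be a named vector of event codes")
  bad <- setdiff(ev, registry$codes)
  if (length(bad))
    stop_format("unknown event code(s) for taxon '%s': %s", taxon,
                paste(bad, collapse = ", "))
  if (anyDuplicated(ev))
    stop_format("duplicate event(s) for taxon '%s': %s", taxon,
                paste(unique(ev[duplicated(ev)]), collapse = ", "))
  onset <- setNames(rep(NA_real_, length(registry$codes)), registry$codes)
  status <- setNames(rep("unknown", length(registry$codes)), registry$codes)
  for (e in ev) {
    v <- onsets[[e]]
    if (is.character(v) && v %in% c("never", "unknown")) {
      status[e] <- v
    } else {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num) || !is.finite(num))
        stop_format("onset for (%s, %s) must be a finite number, 'never' or 'unknown' (got '%s')",
                    taxon, e, as.character(v))
      onset[e] <- num
      status[e] <- "observed"
    }
  }
  structure(list(taxon = as.character(taxon), onset = onset, status = status),
            class = "ossification_timeline")
}

#' @export
print.ossification_timeline <- function(x, ...) {
  cat("Ossification timeline for", x$taxon, "\n")
  shown <- ifelse(x$status == "observed", format(x$onset), x$status)
  print(setNames(shown, names(x$status)), quote = FALSE)
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the policy choices shared by the pipeline stages plus the random
#' seed, so that every report can record exactly how it was produced.
#'
#' @param never_policy How never-ossifying events enter comparisons:
#'   `"last"` (they rank after every observed onset; two such events are
#'   simultaneous) or `"missing"` (scored as missing data).
#' @param tie_policy Rank tie handling; only `"average_rank"` is defined.
#' @param pair_order Event-pair column order; only `"registry"` is defined.
#' @param parsimony_mode Character-state model; only `"unordered"` is defined.
#' @param ambiguity_report Which resolutions reports include: `"acctran"`,
#'   `"deltran"`, or `"mpr_union"`.
#' @param seed Integer random seed recorded in reports and used by all
#'   stochastic operations.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(never_policy = c("last", "missing"),
                            tie_policy = "average_rank",
                            pair_order = "registry",
                            parsimony_mode = "unordered",
                            ambiguity_report = c("mpr_union", "acctran", "deltran"),
                            seed = 1L) {
  never_policy <- match.arg(never_policy)
  ambiguity_report <- match.arg(ambiguity_report)
  tie_policy <- match.arg(tie_policy)
  pair_order <- match.arg(pair_order)
  parsimony_mode <- match.arg(parsimony_mode)
  structure(list(never_policy = never_policy, tie_policy = tie_policy,
                 pair_order = pair_order, parsimony_mode = parsimony_mode,
                 ambiguity_report = ambiguity_report,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read a delimited event-onset table
#'
#' Parses a comma-delimited table with header columns `taxon`, `event`,
#' `onset` into one [timeline()] per taxon. The `onset` field is a number
#' or one of `never` / `unknown`; events absent from the table are scored
#' `unknown`.
#'
#' @param text Table text (single string or character vector of lines), or
#'   a file path via `file=`.
#' @param registry An [event_registry()].
#' @param file Optional path to read instead of `text`.
#' @return A list of `ossification_timeline` objects, one per taxon, in
#'   first-appearance order.
#' @examples
#' reg <- default_registry()
#' txt <- "taxon,event,onset\nPsin,CBI,29\nPsin,EPI,never"
#' read_event_table(txt, reg)
#' @export
read_event_table <- function(text, registry, file = NULL) {
  stopifnot(inherits(registry, "event_registry"))
  if (!is.null(file)) {
    df <- tryCatch(read.csv(file, stringsAsFactors = FALSE,
                            strip.white = TRUE),
                   error = function(e) stop_format("cannot read event table: %s",
                                                   conditionMessage(e)))
  } else {
    if (length(text) > 1L) text <- paste(text, collapse = "\n")
    df <- tryCatch(read.csv(text = text, stringsAsFactors = FALSE,
                            strip.white = TRUE),
                   error = function(e) stop_format("cannot parse event table: %s",
                                                   conditionMessage(e)))
  }
  need <- c("taxon", "event", "onset")
  names(df) <- tolower(names(df))
  if (!all(need %in% names(df)))
    stop_format("event table header must name columns taxon, event, onset (got: %s)",
                paste(names(df), collapse = ", "))
  if (nrow(df) == 0L) return(list())
  bad <- which(!(df$event %in% registry$codes))
  if (length(bad))
    stop_format("row %d: unknown event code '%s'", bad[1L], df$event[bad[1L]])
  dup <- which(duplicated(df[c("taxon", "event")]))
  if (length(dup))
    stop_format("row %d: duplicate entry for (%s, %s)", dup[1L],
                df$taxon[dup[1L]], df$event[dup[1L]])
  taxa <- unique(df$taxon)
  lapply(taxa, function(tx) {
    sub <- df[df$taxon == tx, , drop = FALSE]
    timeline(tx, setNames(as.list(sub$onset), sub$event), registry)
  })
}
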