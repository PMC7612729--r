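ENHANCER_STATES <- c("active", "mixed", "primed", "poised", "repressed",
                     "neutral")
PROMOTER_STATES <- c("active", "mixed", "poised", "repressed", "neutral")

#' Read a chromatin-state truth table
#'
#' The truth table maps every combination of mark presence/absence flags to
#' a chromatin state, separately for enhancers (H3K4me1/H3K27ac/H3K27me3)
#' and promoters (H3K4me3/H3K27ac/H3K27me3). It is shipped as a versioned
#' YAML config so the mapping is auditable and overridable without code
#' changes; the package default encodes: active = acetylated without
#' Polycomb, mixed = acetylation together with H3K27me3, primed = H3K4me1
#' only, poised = H3K4me1 (promoters: H3K4me3) plus H3K27me3 without
#' acetylation, repressed = H3K27me3 alone, neutral = no mark.
#'
#' @param path YAML file; defaults to the config shipped with the package.
#' @return a list with components \code{enhancer} and \code{promoter}, each
#'   holding \code{marks} (ordered mark names) and \code{states} (named map
#'   from binary flag string to state).
#' @export
read_truth_table <- function(path = system.file("extdata",
                                                "truth_tables.yaml",
                                                package = "chromtrace")) {
  tt <- yaml::read_yaml(path)
  for (kind in c("enhancer", "promoter")) {
    k <- tt[[kind]]
    if (is.null(k$marks) || is.null(k$states))
      stop("truth table lacks marks/states for ", kind, call. = FALSE)
    want <- apply(expand.grid(rep(list(0:1), length(k$marks))), 1, paste,
                  collapse = "")
    miss <- setdiff(want, names(k$states))
    if (length(miss))
      stop("truth table for ", kind, " misses combination(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  tt
}

#' Classify regulatory elements into chromatin states
#'
#' For every element and cell type, a mark flag is set when the element is
#' covered to at least \code{min_overlap_frac} of its length by the union
#' of that mark's peaks in that cell type; the flag combination is then
#' looked up in the truth table. Elements with no flag set are neutral.
#'
#' @param elements \code{GRanges} with an \code{element_id} column, from
#'   [build_enhancer_set()] or [build_promoter_set()].
#' @param mark_peaks nested named list: \code{mark_peaks[[mark]][[cell_type]]}
#'   is a \code{GRanges} of that mark's reproducible peaks. All marks of the
#'   element kind must be present for every requested cell type.
#' @param cell_types character vector of cell types to classify.
#' @param kind "enhancer" or "promoter"; selects the marks and table.
#' @param min_overlap_frac flag threshold on covered fraction (default 0.2).
#' @param truth_table from [read_truth_table()].
#' @return data.frame with columns \code{element_id}, \code{cell_type},
#'   \code{state} and one logical flag column per mark.
#' @export
classify_elements <- function(elements, mark_peaks, cell_types,
                              kind = c("enhancer", "promoter"),
                              min_overlap_frac = 0.2,
                              truth_table = read_truth_table()) {
  kind <- match.arg(kind)
  .assert_granges(elements, "elements")
  marks <- truth_table[[kind]]$marks
  states_map <- truth_table[[kind]]$states
  gaps <- character()
  for (m in marks) for (ct in cell_types)
    if (is.null(mark_peaks[[m]][[ct]]))
      gaps <- c(gaps, paste0(m, "/", ct))
  if (length(gaps))
    stop("missing peak set(s): ", paste(gaps, collapse = ", "),
         call. = FALSE)
  out <- vector("list", length(cell_types))
  for (i in seq_along(cell_types)) {
    ct <- cell_types[i]
    flags <- vapply(marks, function(m)
      overlap_fraction(elements, mark_peaks[[m]][[ct]]) >= min_overlap_frac,
      logical(length(elements)))
    flags <- matrix(flags, ncol = length(marks),
                    dimnames = list(NULL, marks))
    key <- apply(flags, 1, function(f) paste(as.integer(f), collapse = ""))
    df <- data.frame(element_id = elements$element_id, cell_type = ct,
                     state = unlist(states_map[key], use.names = FALSE),
                     stringsAsFactors = FALSE)
    for (m in marks) df[[m]] <- flags[, m]
    out[[i]] <- df
  }
  do.call(rbind, out)
}

#' Tally chromatin-state transitions between consecutive cell types
#'
#' @param assignments data.frame from [classify_elements()].
#' @param ordered_cell_types trajectory order; one transition matrix is
#'   produced per consecutive pair.
#' @param element_ids optional subset of elements (e.g. those active in a
#'   terminal cell type) to track.
#' @param states state levels fixing row/column order; defaults to the
#'   states present.
#' @return named list of count matrices (source state in rows, target state
#'   in columns), names "A->B".
#' @export
state_transitions <- function(assignments, ordered_cell_types,
                              element_ids = NULL, states = NULL) {
  stopifnot(length(ordered_cell_types) >= 2)
  if (!is.null(element_ids))
    assignments <- assignments[assignments$element_id %in% element_ids, ,
                               drop = FALSE]
  states <- states %||% sort(unique(assignments$state))
  wide <- split(assignments$state, assignments$cell_type)
  ids <- split(assignments$element_id, assignments$cell_type)
  for (ct in ordered_cell_types)
    if (is.null(wide[[ct]]))
      stop("no state assignments for cell type ", ct, call. = FALSE)
  out <- list()
  for (i in seq_len(length(ordered_cell_types) - 1)) {
    a <- ordered_cell_types[i]; b <- ordered_cell_types[i + 1]
    sa <- wide[[a]][order(ids[[a]])]
    sb <- wide[[b]][order(ids[[b]])]
    if (length(sa) != length(sb) ||
        !identical(sort(ids[[a]]), sort(ids[[b]])))
      stop("element sets differ between ", a, " and ", b, call. = FALSE)
    if (anyNA(sa) || anyNA(sb))
      stop("element with missing state in ", a, " or ", b, call. = FALSE)
    out[[paste0(a, "->", b)]] <- table(
      factor(sa, levels = states), factor(sb, levels = states))
  }
  out
}

#' State counts and fractions in one cell type
#'
#' @param assignments data.frame from [classify_elements()].
#' @param cell_type cell type to summarise.
#' @param states state levels fixing the output order.
#' @return data.frame with columns \code{state}, \code{count},
#'   \code{fraction}; fractions sum to 1.
#' @export
state_fractions <- function(assignments, cell_type, states = NULL) {
  sub <- assignments[assignments$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0) stop("no assignments for ", cell_type, call. = FALSE)
  states <- states %||% sort(unique(assignments$state))
  counts <- table(factor(sub$state, levels = states))
  data.frame(state = states, count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(sub),
             stringsAsFactors = FALSE)
}
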