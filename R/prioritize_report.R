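#' Cohort diagnostic yield
#'
#' Fraction of quality-passing samples in which a pathogenic or likely
#' pathogenic variant was identified, expressed as a whole-number percent
#' (rounded half away from zero, so 9 of 29 gives 31%).
#'
#' @param n_pathogenic Number of samples with (likely) pathogenic findings.
#' @param n_passed_qc Number of samples passing quality control (>= 1).
#' @param n_tested Total samples tested; defaults to `n_passed_qc`.
#' @return An object of class `yield_summary`: list with `n_tested`,
#'   `n_passed_qc`, `n_pathogenic`, `yield_percent`.
#' @export
#' @examples
#' compute_yield(9, 29)$yield_percent
compute_yield <- function(n_pathogenic, n_passed_qc, n_tested = n_passed_qc) {
  if (n_passed_qc < 1) stop("n_passed_qc must be >= 1")
  if (n_pathogenic < 0 || n_pathogenic > n_passed_qc) {
    stop("need 0 <= n_pathogenic <= n_passed_qc")
  }
  if (n_passed_qc > n_tested) stop("n_passed_qc cannot exceed n_tested")
  pct <- 100 * n_pathogenic / n_passed_qc
  structure(list(n_tested = as.integer(n_tested),
                 n_passed_qc = as.integer(n_passed_qc),
                 n_pathogenic = as.integer(n_pathogenic),
                 yield_percent = floor(pct + 0.5)),  # half away from zero
            class = "yield_summary")
}

#' @export
print.yield_summary <- function(x, ...) {
  cat(sprintf("diagnostic yield: %d%% (%d/%d)\n", x$yield_percent,
              x$n_pathogenic, x$n_passed_qc))
  invisible(x)
}

#' Flag genes by dosage-sensitivity scores
#'
#' Sets `haplo_flag` when `pHaplo >= haplo_threshold` (deletion-sensitive)
#' and `triplo_flag` when `pTriplo >= triplo_threshold`
#' (duplication-sensitive); both comparisons are boundary-inclusive. The
#' default thresholds (0.55 / 0.68) are the operating points used for
#' candidate selection in this pipeline; `preset = "published"` switches to
#' the commonly published 0.86 / 0.94 cutoffs. Missing scores never flag
#' and are recorded in the `missing_score` column.
#'
#' @param dosage Data.frame with `symbol` and at least `pHaplo`, `pTriplo`
#'   (columns `pLI`, `LOEUF`, `sHet` are carried through when present).
#' @param haplo_threshold,triplo_threshold Thresholds in \[0,1\].
#' @param preset `"default"` (0.55/0.68) or `"published"` (0.86/0.94);
#'   explicit threshold arguments win over the preset.
#' @return The input with logical columns `haplo_flag`, `triplo_flag`,
#'   `missing_score` appended.
#' @export
#' @examples
#' flag_dosage(data.frame(symbol = "NPEPPS", pHaplo = 0.86, pTriplo = 0.85))
flag_dosage <- function(dosage, haplo_threshold = NULL,
                        triplo_threshold = NULL,
                        preset = c("default", "published")) {
  preset <- match.arg(preset)
  def <- if (preset == "default") c(0.55, 0.68) else c(0.86, 0.94)
  ht <- if (is.null(haplo_threshold)) def[1] else haplo_threshold
  tt <- if (is.null(triplo_threshold)) def[2] else triplo_threshold
  if (ht < 0 || ht > 1 || tt < 0 || tt > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  stopifnot(all(c("symbol", "pHaplo", "pTriplo") %in% names(dosage)))
  dosage$haplo_flag <- !is.na(dosage$pHaplo) & dosage$pHaplo >= ht
  dosage$triplo_flag <- !is.na(dosage$pTriplo) & dosage$pTriplo >= tt
  dosage$missing_score <- is.na(dosage$pHaplo) | is.na(dosage$pTriplo)
  dosage
}

#' Assemble the candidate-gene report
#'
#' Joins the CNV-derived gene table with smallest-interactome membership,
#' disease-panel membership, topological role labels and dosage flags into
#' one row per CNV gene, plus a summary block of overlap counts. The
#' summary's `n_smallest_union` applies inclusion-exclusion to the two
#' membership groups within the smallest interactome:
#' `|CNV in smallest| + |panel in smallest| - |both in smallest|`.
#'
#' @param cnv_genes Data.frame with `symbol` and `cnv_origin`
#'   (`loss`/`gain`); duplicate symbols are an error.
#' @param smallest_members Character vector: nodes of the smallest
#'   (diffusion-selected) interactome.
#' @param ndd_panel Character vector: disease-panel gene symbols.
#' @param roles Optional output of [classify_roles()].
#' @param dosage Optional output of [flag_dosage()] (or a raw dosage table,
#'   which is flagged with default thresholds).
#' @return An object of class `candidate_report`: list with `candidates`
#'   (data.frame sorted by membership, flags and hub axis) and `summary`
#'   (named list of counts).
#' @export
assemble_candidates <- function(cnv_genes, smallest_members, ndd_panel,
                                roles = NULL, dosage = NULL) {
  stopifnot(all(c("symbol", "cnv_origin") %in% names(cnv_genes)))
  norm <- function(x) toupper(as.character(x))
  cnv_genes$symbol <- norm(cnv_genes$symbol)
  smallest_members <- unique(norm(smallest_members))
  ndd_panel <- unique(norm(ndd_panel))
  dup <- unique(cnv_genes$symbol[duplicated(cnv_genes$symbol)])
  if (length(dup)) stop("duplicate symbols in cnv_genes: ",
                        paste(dup, collapse = ", "))
  if (!all(cnv_genes$cnv_origin %in% c("loss", "gain"))) {
    stop("cnv_origin must be \"loss\" or \"gain\"")
  }
  out <- data.frame(symbol = cnv_genes$symbol,
                    cnv_origin = cnv_genes$cnv_origin,
                    in_smallest = cnv_genes$symbol %in% smallest_members,
                    in_ndd_panel = cnv_genes$symbol %in% ndd_panel,
                    stringsAsFactors = FALSE)
  if (!is.null(roles)) {
    roles$node <- norm(roles$node)
    dup <- unique(roles$node[duplicated(roles$node)])
    if (length(dup)) stop("duplicate symbols in roles: ",
                          paste(dup, collapse = ", "))
    idx <- match(out$symbol, roles$node)
    out$hub_axis <- roles$hub_axis[idx]
    out$integration_axis <- roles$integration_axis[idx]
  } else {
    out$hub_axis <- rep(NA_character_, nrow(out))
    out$integration_axis <- rep(NA_character_, nrow(out))
  }
  if (!is.null(dosage)) {
    dosage$symbol <- norm(dosage$symbol)
    dup <- unique(dosage$symbol[duplicated(dosage$symbol)])
    if (length(dup)) stop("duplicate symbols in dosage: ",
                          paste(dup, collapse = ", "))
    if (!"haplo_flag" %in% names(dosage)) dosage <- flag_dosage(dosage)
    idx <- match(out$symbol, dosage$symbol)
    for (col in c("pLI", "LOEUF", "sHet", "pHaplo", "pTriplo")) {
      if (col %in% names(dosage)) out[[col]] <- dosage[[col]][idx]
    }
    out$haplo_flag <- !is.na(idx) & dosage$haplo_flag[idx]
    out$triplo_flag <- !is.na(idx) & dosage$triplo_flag[idx]
    # headline flag pairs deletion-sensitivity with loss, duplication-
    # sensitivity with gain
    out$headline_flag <- ifelse(out$cnv_origin == "loss", out$haplo_flag,
                                out$triplo_flag)
  } else {
    out$haplo_flag <- rep(FALSE, nrow(out))
    out$triplo_flag <- rep(FALSE, nrow(out))
    out$headline_flag <- rep(FALSE, nrow(out))
  }
  hub_rank <- match(out$hub_axis, c("hub", "connector_bottleneck",
                                    "provincial_hub", "peripheral"))
  hub_rank[is.na(hub_rank)] <- 5L
  ord <- order(-out$in_smallest, -out$headline_flag,
               -(out$haplo_flag | out$triplo_flag), hub_rank, out$symbol)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL

  cnv_in_small <- intersect(cnv_genes$symbol, smallest_members)
  panel_in_small <- intersect(ndd_panel, smallest_members)
  both_in_small <- intersect(cnv_in_small, panel_in_small)
  summary <- list(
    n_cnv_genes = nrow(cnv_genes),
    n_smallest_members = length(smallest_members),
    n_panel_genes = length(ndd_panel),
    n_cnv_in_smallest = length(cnv_in_small),
    n_panel_in_smallest = length(panel_in_small),
    n_cnv_panel_in_smallest = length(both_in_small),
    n_smallest_union = length(cnv_in_small) + length(panel_in_small) -
      length(both_in_small)
  )
  structure(list(candidates = out, summary = summary),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<candidate_report> %d CNV genes | %d in smallest ",
                     "interactome | %d also in panel\n"),
              s$n_cnv_genes, s$n_cnv_in_smallest, s$n_cnv_panel_in_smallest))
  print.data.frame(utils::head(x$candidates, 10), ...)
  if (nrow(x$candidates) > 10) {
    cat("...", nrow(x$candidates) - 10, "more rows\n")
  }
  invisible(x)
}

#' Write a candidate report to TSV and JSON
#'
#' Output is byte-stable for a fixed report: numbers are serialized at full
#' precision and row order is the report's canonical order. The JSON carries
#' a `schema_version` field.
#'
#' @param report A `candidate_report` from [assemble_candidates()].
#' @param dir Output directory (created if absent).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, formats = c("tsv", "json")) {
  stopifnot(inherits(report, "candidate_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  if ("tsv" %in% formats) {
    p <- file.path(dir, "candidates.tsv")
    write.table(report$candidates, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, tsv = p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "candidates.json")
    payload <- list(schema_version = "1.0",
                    summary = report$summary,
                    candidates = report$candidates)
    jsonlite::write_json(payload, p, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows", na = "null")
    paths <- c(paths, json = p)
  }
  invisible(paths)
}

#' Read back a JSON candidate report
#'
#' Inverse of the JSON branch of [write_report()].
#'
#' @param path Path to `candidates.json`.
#' @return A `candidate_report`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::fromJSON(path)
  cand <- payload$candidates
  if (is.null(cand) || !length(cand)) {
    cand <- data.frame(symbol = character(), cnv_origin = character(),
                       stringsAsFactors = FALSE)
  }
  structure(list(candidates = as.data.frame(cand),
                 summary = payload$summary),
            class = "candidate_report")
}

#' Top-k term slots per group
#'
#' Generic "top-k per group" bookkeeping used for functional-module
#' summaries: for each group, retain the `k` highest-scoring terms (ties
#' broken alphabetically by term). With 47 modules and k = 5 this yields
#' 235 extracted term slots.
#'
#' @param terms Data.frame with group, term and score columns.
#' @param k Terms to keep per group.
#' @param group_col,term_col,score_col Column names.
#' @return Data.frame of the selected rows with an `n_slots` attribute
#'   (its row count) and an `n_unique_terms` attribute.
#' @export
select_top_terms <- function(terms, k = 5L, group_col = "module",
                             term_col = "term", score_col = "score") {
  stopifnot(all(c(group_col, term_col, score_col) %in% names(terms)))
  pieces <- split(terms, terms[[group_col]])
  sel <- lapply(pieces, function(p) {
    p <- p[order(-p[[score_col]], p[[term_col]]), , drop = FALSE]
    utils::head(p, k)
  })
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  attr(out, "n_slots") <- nrow(out)
  attr(out, "n_unique_terms") <- length(unique(out[[term_col]]))
  out
}
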