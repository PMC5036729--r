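#' Read and write decision problems
#'
#' Problem files are JSON (always available) or YAML (if the `yaml`
#' package is installed) with keys:
#' \describe{
#'   \item{alternatives}{list of labels,}
#'   \item{criteria}{list of `{name, weight}` records,}
#'   \item{relations}{map from criterion name to an n x n matrix of
#'     `"membership,nonmembership"` cells (decimals or fractions).}
#' }
#' Parsing is followed by full structural and preference-relation
#' validation; every error message carries the offending file, key or
#' cell.
#'
#' @param path file to read or write.
#' @param format `"auto"` (by extension), `"json"` or `"yaml"`.
#' @param scale_mode,strict_weights passed to [decision_problem()].
#' @return `load_problem()`: a [decision_problem]; `save_problem()`:
#'   `path`, invisibly.
#' @examples
#' f <- system.file("extdata", "mwdms.json", package = "icrdm")
#' p <- load_problem(f)
#' @export
load_problem <- function(path, format = c("auto", "json", "yaml"),
                         scale_mode = TRUE, strict_weights = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) contract_error(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  raw <- if (format == "yaml") {
    if (!requireNamespace("yaml", quietly = TRUE))
      contract_error("YAML input requires the 'yaml' package; use JSON instead")
    tryCatch(yaml::read_yaml(path), error = function(e)
      contract_error(sprintf("%s: YAML parse error: %s", path, conditionMessage(e))))
  } else {
    tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE), error = function(e)
      contract_error(sprintf("%s: JSON parse error: %s", path, conditionMessage(e))))
  }
  for (key in c("alternatives", "criteria", "relations"))
    if (is.null(raw[[key]]))
      contract_error(sprintf("%s: missing required key '%s'", path, key))
  alternatives <- vapply(raw$alternatives, as.character, character(1))
  crit_names <- vapply(raw$criteria, function(cr) {
    if (is.null(cr$name)) contract_error(sprintf("%s: criterion without a 'name'", path))
    as.character(cr$name)
  }, character(1))
  crit_weights <- vapply(raw$criteria, function(cr) {
    if (is.null(cr$weight) || !is.numeric(cr$weight))
      contract_error(sprintf("%s: criterion '%s' needs a numeric 'weight'", path, cr$name))
    as.numeric(cr$weight)
  }, numeric(1))
  n <- length(alternatives)
  relations <- lapply(crit_names, function(nm) {
    rel <- raw$relations[[nm]]
    if (is.null(rel))
      contract_error(sprintf("%s: no relation for criterion '%s'", path, nm))
    rows <- lapply(rel, function(r) vapply(r, as.character, character(1)))
    if (any(vapply(rows, length, integer(1)) != n) || length(rows) != n)
      contract_error(sprintf("%s: relation '%s' is not %d x %d", path, nm, n, n))
    cells <- do.call(rbind, rows)
    tryCatch(ipr(cells, labels = alternatives), icrdm_error = function(e)
      .icrdm_error(sprintf("%s: relation '%s': %s", path, nm,
                           conditionMessage(e)), class(e)[1]))
  })
  names(relations) <- crit_names
  decision_problem(alternatives, crit_names, crit_weights, relations,
                   scale_mode = scale_mode, strict_weights = strict_weights)
}

#' @rdname load_problem
#' @param p a [decision_problem].
#' @export
save_problem <- function(p, path, format = c("auto", "json", "yaml")) {
  stopifnot(inherits(p, "decision_problem"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  rel <- lapply(p$relations, function(r) {
    n <- nrow(r$mu)
    lapply(seq_len(n), function(i)
      as.list(paste0(fmt_g15(r$mu[i, ]), ",", fmt_g15(r$nu[i, ]))))
  })
  obj <- list(
    alternatives = as.list(p$alternatives),
    criteria = lapply(seq_along(p$criteria), function(l)
      list(name = p$criteria[l], weight = p$weights[l])),
    relations = rel)
  if (format == "yaml") {
    if (!requireNamespace("yaml", quietly = TRUE))
      contract_error("YAML output requires the 'yaml' package; use JSON instead")
    yaml::write_yaml(obj, path, precision = 15)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a ranking report
#'
#' JSON reports carry full-precision numbers plus a parallel 4-decimal
#' `display` rendering and a `schema_version`; the text format prints the
#' local-priority decision matrix, overall priorities, scores and the
#' ranking in the layout of the published tables.
#'
#' @param r a `ranking_result` from [solve_decision()].
#' @param path output file, or `NULL` to return the report as a character
#'   vector.
#' @param format `"json"` or `"text"`.
#' @return the report lines, invisibly when written to `path`.
#' @export
write_report <- function(r, path = NULL, format = c("json", "text")) {
  stopifnot(inherits(r, "ranking_result"))
  format <- match.arg(format)
  lines <- if (format == "json") report_json(r) else report_text(r)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

report_json <- function(r) {
  B <- r$decision_matrix
  disp <- function(v) formatC(v, digits = 4, format = "f")
  obj <- list(
    schema_version = "1.0",
    library_version = as.character(packageVersion("icrdm")),
    score_variant = r$score_variant,
    alternatives = as.list(r$alternatives),
    criteria = as.list(r$criteria),
    weights = r$weights,
    decision_matrix = list(
      membership = unname(apply(B$mu, 1, as.list, simplify = FALSE)),
      nonmembership = unname(apply(B$nu, 1, as.list, simplify = FALSE)),
      display = unname(apply(format(B), 1, as.list, simplify = FALSE))),
    overall = lapply(seq_along(r$alternatives), function(i) list(
      alternative = r$alternatives[i],
      membership = r$overall$mu[i],
      nonmembership = r$overall$nu[i],
      score = r$scores[i],
      accuracy = r$accuracies[i],
      display = sprintf("(%s, %s)", disp(r$overall$mu[i]), disp(r$overall$nu[i])))),
    ranking = as.list(r$ranking),
    tie_groups = lapply(r$tie_groups, function(g) as.list(r$alternatives[g])),
    ranking_string = r$ranking_string)
  strsplit(as.character(
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)),
    "\n", fixed = TRUE)[[1]]
}

report_text <- function(r) {
  B <- format(r$decision_matrix)
  widths <- pmax(nchar(colnames(B)), apply(nchar(B), 2, max))
  lab_w <- max(nchar(r$alternatives))
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  hdr <- trimws(paste(c(pad("", lab_w), mapply(pad, colnames(B), widths)),
                      collapse = "  "), which = "right")
  rows <- vapply(seq_len(nrow(B)), function(i)
    trimws(paste(c(pad(r$alternatives[i], lab_w), mapply(pad, B[i, ], widths)),
                 collapse = "  "), which = "right"),
    character(1))
  c("Decision matrix (local priorities):", hdr, rows, "",
    "Overall priorities:",
    sprintf("%s  %s  score %s  accuracy %s",
            formatC(r$alternatives, width = lab_w, flag = "-"),
            format(r$overall),
            formatC(r$scores, digits = 4, format = "f"),
            formatC(r$accuracies, digits = 4, format = "f")), "",
    paste0("Ranking (", r$score_variant, " score): ", r$ranking_string))
}
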