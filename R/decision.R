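#' Two-level hierarchical decision problems
#'
#' A decision problem holds `n` alternatives, `m` criteria with a
#' real-valued weight vector summing to 1, and one intuitionistic
#' preference relation over the alternatives per criterion -- the two-level
#' hierarchy "objective / criteria / alternatives".
#'
#' @param alternatives character vector of alternative labels.
#' @param criteria character vector of criterion labels.
#' @param weights numeric criterion weights (validated by
#'   [weight_vector()]).
#' @param relations list of [ipr] objects, one per criterion (named or in
#'   criterion order), all of dimension `length(alternatives)`.
#' @param scale_mode enforce the \[0.1, 0.9\] rating-scale bounds when
#'   validating relations (default `TRUE`).
#' @param strict_weights passed to [weight_vector()].
#' @return an object of class `decision_problem`.
#' @seealso [decision_matrix()], [solve_decision()], [mwdms_problem()]
#' @export
decision_problem <- function(alternatives, criteria, weights, relations,
                             scale_mode = TRUE, strict_weights = TRUE) {
  alternatives <- as.character(alternatives)
  criteria <- as.character(criteria)
  n <- length(alternatives); m <- length(criteria)
  if (n < 2) contract_error("need at least two alternatives")
  if (m < 1) contract_error("need at least one criterion")
  weights <- weight_vector(weights, strict = strict_weights)
  if (length(weights) != m)
    contract_error(sprintf("%d criteria but %d weights", m, length(weights)))
  if (!is.list(relations) || length(relations) != m)
    contract_error(sprintf("expected %d preference relations, got %d",
                           m, length(relations)))
  if (!is.null(names(relations)) && all(criteria %in% names(relations)))
    relations <- relations[criteria]
  for (l in seq_len(m)) {
    r <- relations[[l]]
    if (!is_ipr(r))
      contract_error(sprintf("relation for criterion '%s' is not an ipr", criteria[l]))
    if (nrow(r$mu) != n)
      contract_error(sprintf(
        "relation for criterion '%s' is %d x %d but there are %d alternatives",
        criteria[l], nrow(r$mu), ncol(r$mu), n))
    rep <- validate_ipr(r, scale_mode = scale_mode)
    if (!attr(rep, "valid"))
      validation_error(sprintf("invalid preference relation for criterion '%s':\n  %s",
                               criteria[l], paste(rep$message, collapse = "\n  ")))
    relations[[l]]$labels <- alternatives
  }
  names(relations) <- criteria
  structure(list(alternatives = alternatives, criteria = criteria,
                 weights = weights, relations = relations,
                 scale_mode = scale_mode),
            class = "decision_problem")
}

#' @export
print.decision_problem <- function(x, ...) {
  cat("<decision_problem>\n")
  cat("  alternatives:", paste(x$alternatives, collapse = ", "), "\n")
  cat("  criteria:    ",
      paste(sprintf("%s (w=%.4g)", x$criteria, x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Local-priority decision matrix
#'
#' Aggregates each preference relation row-wise with the cross-ratio
#' geometric mean, producing the n x m matrix of local priorities: entry
#' (i, l) is the priority of alternative i under criterion l.
#'
#' @param p a [decision_problem].
#' @return an object of class `ifv_matrix`: list of numeric matrices `mu`
#'   and `nu` with alternative/criterion dimnames.
#' @export
decision_matrix <- function(p) {
  stopifnot(inherits(p, "decision_problem"))
  n <- length(p$alternatives); m <- length(p$criteria)
  mu <- matrix(NA_real_, n, m, dimnames = list(p$alternatives, p$criteria))
  nu <- mu
  for (l in seq_len(m)) {
    b <- local_priorities(p$relations[[l]], validate = FALSE)
    mu[, l] <- b$mu; nu[, l] <- b$nu
  }
  structure(list(mu = mu, nu = nu), class = "ifv_matrix")
}

#' @export
format.ifv_matrix <- function(x, digits = 4, ...) {
  out <- matrix(sprintf("(%s, %s)",
                        formatC(x$mu, digits = digits, format = "f"),
                        formatC(x$nu, digits = digits, format = "f")),
                nrow(x$mu), ncol(x$mu), dimnames = dimnames(x$mu))
  out
}

#' @export
print.ifv_matrix <- function(x, digits = 4, ...) {
  print(format(x, digits = digits), quote = FALSE)
  invisible(x)
}

#' Solve a hierarchical decision problem
#'
#' Runs the full procedure: row-wise local priorities per criterion
#' ([decision_matrix()]), fusion of each alternative's local priorities
#' with the criterion weights via [icrwg()], scoring and accuracy
#' evaluation, and a descending ranking under [ifv_compare()] with ties
#' grouped (equal score and accuracy) and ordered by input position.
#'
#' @param p a [decision_problem].
#' @param score_variant `"geometric"` (default) or `"eq4"`; the induced
#'   ranking is identical for both, only the reported score values differ.
#' @return an object of class `ranking_result`: list with
#'   `decision_matrix`, `overall` (`ifv` of overall priorities), `scores`,
#'   `accuracies`, `order`, `tie_groups`, `ranking` (labels, best first)
#'   and `ranking_string`.
#' @examples
#' res <- solve_decision(mwdms_problem())
#' res$ranking_string   # "x1 > x2 > x5 > x3 > x4"
#' @export
solve_decision <- function(p, score_variant = c("geometric", "eq4")) {
  stopifnot(inherits(p, "decision_problem"))
  score_variant <- match.arg(score_variant)
  B <- decision_matrix(p)
  n <- length(p$alternatives)
  overall <- do.call(c, lapply(seq_len(n), function(i)
    icrwg(new_ifv(B$mu[i, ], B$nu[i, ]), p$weights)))
  scores <- ifv_score(overall, variant = score_variant)
  accuracies <- ifv_accuracy(overall)
  rk <- ifv_rank(overall, labels = p$alternatives)
  structure(list(
    alternatives = p$alternatives, criteria = p$criteria,
    weights = p$weights, score_variant = score_variant,
    decision_matrix = B, overall = overall,
    scores = scores, accuracies = accuracies,
    order = rk$order, tie_groups = rk$tie_groups,
    ranking = p$alternatives[rk$order],
    ranking_string = rk$ranking_string),
    class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, digits = 4, ...) {
  cat("Decision matrix (local priorities):\n")
  print(format(x$decision_matrix, digits = digits), quote = FALSE)
  cat("\nOverall priorities:\n")
  tab <- data.frame(
    priority = format(x$overall, digits = digits),
    score = formatC(x$scores, digits = digits, format = "f"),
    accuracy = formatC(x$accuracies, digits = digits, format = "f"),
    row.names = x$alternatives)
  print(tab)
  cat("\nRanking (", x$score_variant, " score): ", x$ranking_string, "\n", sep = "")
  invisible(x)
}
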