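#' Intuitionistic preference relations
#'
#' An IPR is a square matrix of intuitionistic fuzzy values recording
#' pairwise preferences among `n` alternatives: entry (i, j) holds the
#' membership degree to which alternative i is preferred to j and the
#' non-membership degree to which it is not. A valid IPR has the
#' indifference value (0.5, 0.5) on the diagonal and is
#' complement-reciprocal: entry (j, i) is the component swap of entry
#' (i, j). Under the bounded rating scale (the default `scale_mode`),
#' every component additionally lies in \[0.1, 0.9\].
#'
#' `ipr()` constructs from two numeric matrices (memberships and
#' non-memberships) or from a single character matrix of
#' `"membership,nonmembership"` cells (fractions allowed, see
#' [parse_ifv()]). Construction does not enforce reciprocity -- files with
#' inconsistent reciprocals should be diagnosed, not silently repaired --
#' so call [validate_ipr()] (or use `fix_reciprocal = TRUE` to rebuild the
#' lower triangle and diagonal from the upper triangle).
#'
#' @param x an n x n character matrix of cells, or a numeric matrix of
#'   memberships (then `nu` must be given).
#' @param nu numeric matrix of non-memberships, when `x` is numeric.
#' @param labels alternative names; defaults to `x1 ... xn`.
#' @param fix_reciprocal if `TRUE`, overwrite the diagonal with (0.5, 0.5)
#'   and the lower triangle with the complement of the upper.
#' @return an object of class `ipr` with fields `mu`, `nu` (n x n numeric
#'   matrices) and `labels`.
#' @examples
#' m <- matrix(c("0.5,0.5", "5/8,1/5",
#'               "1/5,5/8", "0.5,0.5"), 2, 2, byrow = TRUE)
#' r <- ipr(m)
#' validate_ipr(r)
#' @export
ipr <- function(x, nu = NULL, labels = NULL, fix_reciprocal = FALSE) {
  if (is.character(x)) {
    if (!is.matrix(x) || nrow(x) != ncol(x))
      contract_error("cell matrix must be square")
    vals <- parse_ifv(as.vector(x))
    mu <- matrix(vals$mu, nrow(x), ncol(x))
    nuM <- matrix(vals$nu, nrow(x), ncol(x))
  } else {
    if (!is.matrix(x) || !is.numeric(x) || is.null(nu))
      contract_error("supply a character cell matrix, or numeric mu and nu matrices")
    if (!is.matrix(nu) || any(dim(x) != dim(nu)) || nrow(x) != ncol(x))
      contract_error("mu and nu must be square numeric matrices of equal dimension")
    mu <- x; nuM <- nu
  }
  n <- nrow(mu)
  if (is.null(labels)) labels <- paste0("x", seq_len(n))
  if (length(labels) != n) contract_error("labels must match the matrix dimension")
  if (fix_reciprocal) {
    mu0 <- mu; nu0 <- nuM
    diag(mu) <- 0.5; diag(nuM) <- 0.5
    low <- lower.tri(mu)
    mu[low] <- t(nu0)[low]   # entry (j,i) <- complement of entry (i,j)
    nuM[low] <- t(mu0)[low]
  }
  structure(list(mu = mu, nu = nuM, labels = as.character(labels)),
            class = "ipr")
}

#' @export
is_ipr <- function(x) inherits(x, "ipr")

#' @export
dim.ipr <- function(x) dim(x$mu)

#' @export
print.ipr <- function(x, digits = 4, ...) {
  n <- nrow(x$mu)
  cells <- matrix(sprintf("(%s, %s)",
                          formatC(x$mu, digits = digits, format = "f"),
                          formatC(x$nu, digits = digits, format = "f")), n, n)
  dimnames(cells) <- list(x$labels, x$labels)
  cat("<ipr ", n, " x ", n, ">\n", sep = "")
  print(cells, quote = FALSE)
  invisible(x)
}

#' Validate an intuitionistic preference relation
#'
#' Checks every cell against the IPR invariants and reports all
#' violations, one row per offending cell: `row`, `col`, `invariant` (one
#' of `"value"`, `"diagonal"`, `"reciprocity"`, `"scale"`) and a message.
#' An empty report means the relation is valid.
#'
#' @param m an [ipr] object.
#' @param scale_mode check components against the \[0.1, 0.9\] rating-scale
#'   bounds (default `TRUE`).
#' @param tol tolerance for the diagonal and reciprocity checks.
#' @return a data.frame of violations with attribute `valid`
#'   (`TRUE`/`FALSE`); also available as `ipr_is_valid(m, ...)`.
#' @export
validate_ipr <- function(m, scale_mode = TRUE, tol = 1e-9) {
  if (!is_ipr(m)) contract_error("not an ipr object")
  n <- nrow(m$mu)
  rows <- list()
  add <- function(i, j, invariant, msg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      row = i, col = j, invariant = invariant, message = msg,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mu <- m$mu[i, j]; nu <- m$nu[i, j]
    if (!is.finite(mu) || !is.finite(nu) || mu <= 0 || mu >= 1 || nu <= 0 || nu >= 1)
      add(i, j, "value", sprintf("cell (%d,%d): components must lie strictly in (0,1)", i, j))
    else if (mu + nu > 1 + tol)
      add(i, j, "value", sprintf("cell (%d,%d): membership + nonmembership = %.6g > 1", i, j, mu + nu))
    else {
      if (i == j && (abs(mu - 0.5) > tol || abs(nu - 0.5) > tol))
        add(i, j, "diagonal", sprintf("cell (%d,%d): diagonal must be (0.5, 0.5), got (%.4g, %.4g)", i, j, mu, nu))
      if (i < j) {
        if (abs(m$mu[j, i] - nu) > tol || abs(m$nu[j, i] - mu) > tol)
          add(j, i, "reciprocity",
              sprintf("cell (%d,%d): expected complement (%.4g, %.4g) of cell (%d,%d), got (%.4g, %.4g)",
                      j, i, nu, mu, i, j, m$mu[j, i], m$nu[j, i]))
      }
      if (scale_mode && (mu < 0.1 - tol || mu > 0.9 + tol || nu < 0.1 - tol || nu > 0.9 + tol))
        add(i, j, "scale", sprintf("cell (%d,%d): components (%.4g, %.4g) outside the [0.1, 0.9] scale", i, j, mu, nu))
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = integer(0), col = integer(0),
               invariant = character(0), message = character(0),
               stringsAsFactors = FALSE)
  attr(report, "valid") <- nrow(report) == 0L
  report
}

#' @rdname validate_ipr
#' @param ... passed to [validate_ipr()].
#' @export
ipr_is_valid <- function(m, ...) {
  isTRUE(attr(validate_ipr(m, ...), "valid"))
}

#' Row-wise local priorities of an IPR
#'
#' Aggregates each row of the relation (diagonal included) with the
#' cross-ratio geometric mean [icrwgm()], yielding one priority value per
#' alternative. With all cells on the 0.1--0.9 scale the priorities stay on
#' the scale.
#'
#' @param m a valid [ipr].
#' @param validate check validity first (default `TRUE`).
#' @param scale_mode passed to [validate_ipr()] when validating.
#' @return an `ifv` vector of length n, one local priority per alternative.
#' @export
local_priorities <- function(m, validate = TRUE, scale_mode = TRUE) {
  if (!is_ipr(m)) contract_error("not an ipr object")
  if (validate) {
    rep <- validate_ipr(m, scale_mode = scale_mode)
    if (!attr(rep, "valid"))
      validation_error(paste0("invalid preference relation:\n  ",
                              paste(rep$message, collapse = "\n  ")))
  }
  new_ifv(plogis(rowMeans(qlogis(m$mu))),
          plogis(rowMeans(qlogis(m$nu))))
}

#' Random valid preference relations
#'
#' Draws an upper triangle of ratings -- membership uniform on
#' \[0.1, 0.9\], non-membership uniform on \[0.1, min(0.9, 1 - membership)\]
#' -- and fills the diagonal and lower triangle by construction, so the
#' result always validates. Deterministic for a fixed seed; the caller's
#' RNG state is left untouched.
#'
#' @param n number of alternatives (>= 2).
#' @param seed integer seed.
#' @param scale_mode kept for symmetry with [validate_ipr()]; the generator
#'   always draws on the rating scale.
#' @return an [ipr].
#' @export
random_ipr <- function(n, seed, scale_mode = TRUE) {
  if (!is.numeric(n) || n < 2) contract_error("n must be an integer >= 2")
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  mu <- matrix(0.5, n, n); nu <- matrix(0.5, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    m_ij <- runif(1, 0.1, 0.9)
    nu_ij <- runif(1, 0.1, min(0.9, 1 - m_ij))
    mu[i, j] <- m_ij; nu[i, j] <- nu_ij
    mu[j, i] <- nu_ij; nu[j, i] <- m_ij
  }
  ipr(mu, nu)
}

#' Read and write preference relations as CSV
#'
#' One CSV row per matrix row; each cell is a quoted
#' `"membership,nonmembership"` pair, decimals or fractions. An optional
#' leading header row carries alternative labels (recognised because label
#' fields contain no comma). `write_ipr_csv()` emits a canonical form --
#' header plus 15-significant-digit cells -- whose read/write round trip is
#' byte-identical.
#'
#' @param path file path.
#' @param m an [ipr].
#' @return `read_ipr_csv()`: an [ipr]; `write_ipr_csv()`: `path`,
#'   invisibly.
#' @export
read_ipr_csv <- function(path) {
  if (!file.exists(path)) contract_error(sprintf("file not found: %s", path))
  raw <- tryCatch(
    read.csv(path, header = FALSE, colClasses = "character",
             stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) contract_error(sprintf("%s: cannot parse CSV: %s",
                                               path, conditionMessage(e))))
  tab <- as.matrix(raw)
  labels <- NULL
  if (nrow(tab) > 0 && !any(grepl(",", tab[1, ], fixed = TRUE))) {
    labels <- as.character(tab[1, ])
    tab <- tab[-1, , drop = FALSE]
  }
  if (nrow(tab) != ncol(tab))
    contract_error(sprintf("%s: matrix is %d rows by %d columns; an IPR must be square",
                           path, nrow(tab), ncol(tab)))
  n <- nrow(tab)
  mu <- matrix(NA_real_, n, n); nu <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- tryCatch(parse_ifv(tab[i, j]), icrdm_error = function(e)
      .icrdm_error(sprintf("%s: row %d, column %d: %s", path, i, j,
                           conditionMessage(e)), class(e)[1]))
    mu[i, j] <- v$mu; nu[i, j] <- v$nu
  }
  ipr(mu, nu, labels = labels)
}

#' @rdname read_ipr_csv
#' @export
write_ipr_csv <- function(m, path) {
  if (!is_ipr(m)) contract_error("not an ipr object")
  n <- nrow(m$mu)
  cells <- matrix(paste0(fmt_g15(m$mu), ",", fmt_g15(m$nu)), n, n)
  lines <- c(paste(m$labels, collapse = ","),
             apply(cells, 1, function(r) paste(sprintf('"%s"', r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
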