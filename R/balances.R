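#' Define an isometric log-ratio balance scheme
#'
#' A balance scheme is a sequential binary partition (SBP) of the parts of a
#' composition. Each of the D-1 contrasts opposes a denominator group
#' \eqn{c_j^-} to a numerator group \eqn{c_j^+}; the j-th balance is
#' \deqn{b_j = \sqrt{r_j s_j / (r_j + s_j)}\; \ln\left(g(c_j^+)/g(c_j^-)\right)}
#' with \eqn{r_j = |c_j^-|}, \eqn{s_j = |c_j^+|} and g() the geometric mean.
#' We follow the \[denominator parts | numerator parts\] notation: a positive
#' balance means the numerator group dominates.
#'
#' @param name Scheme label.
#' @param parts Character vector of part names (length D >= 2).
#' @param contrasts List of D-1 lists, each with elements `den` and `num`
#'   (character vectors of part names, disjoint, subsets of `parts`).
#' @return An object of class `balance_scheme` carrying the orthonormal
#'   contrast matrix `psi` ((D-1) x D).
#' @export
balance_scheme <- function(name, parts, contrasts) {
  stopifnot(is.character(parts), length(parts) >= 2)
  D <- length(parts)
  if (length(contrasts) != D - 1) {
    stop("a sequential binary partition of ", D, " parts needs exactly ",
         D - 1, " contrasts, got ", length(contrasts))
  }
  psi <- matrix(0, D - 1, D, dimnames = list(NULL, parts))
  labels <- character(D - 1)
  for (j in seq_len(D - 1)) {
    den <- contrasts[[j]]$den
    num <- contrasts[[j]]$num
    if (length(intersect(den, num)) > 0) {
      stop("contrast ", j, ": denominator and numerator sets overlap")
    }
    if (!all(c(den, num) %in% parts)) {
      stop("contrast ", j, ": unknown part name")
    }
    r <- length(den); s <- length(num)
    if (r < 1 || s < 1) stop("contrast ", j, ": both sides must be non-empty")
    coef <- sqrt(r * s / (r + s))
    psi[j, num] <- coef / s
    psi[j, den] <- -coef / r
    labels[j] <- paste0("[", paste(den, collapse = ","), " | ",
                        paste(num, collapse = ","), "]")
  }
  gram <- psi %*% t(psi)
  if (max(abs(gram - diag(D - 1))) > 1e-9) {
    stop("contrasts do not form a sequential binary partition ",
         "(contrast matrix is not orthonormal)")
  }
  structure(list(name = name, parts = parts, contrasts = contrasts,
                 labels = labels, psi = psi),
            class = "balance_scheme")
}

#' @export
print.balance_scheme <- function(x, ...) {
  cat("Balance scheme '", x$name, "' on parts: ",
      paste(x$parts, collapse = ", "), "\n", sep = "")
  for (lab in x$labels) cat("  ", lab, "\n", sep = "")
  invisible(x)
}

#' Balance schemes used for potato trial covariates and targets
#'
#' Returns the standard schemes: soil texture and carbon
#' (\[Sand,Silt,Clay | C\], \[Clay | Sand,Silt\], \[Silt | Sand\]), the P
#' simplex S(P, Al) with filler Fv (\[Fv | Al,P\], \[Al | P\]), the K simplex
#' S(K, Ca, Mg) with filler (\[Fv,Mg,Ca | K\], \[Fv | Mg,Ca\], \[Mg | Ca\]),
#' the soil-type drainage gradient (\[Gleyed | Podzolized\],
#' \[Loamy gleyed | Sandy gleyed\]) and tuber-size fractions
#' (\[M,S | L\], \[S | M\]).
#'
#' @return Named list of `balance_scheme` objects
#'   (`texture`, `chem_p`, `chem_k`, `soil_type`, `tuber_size`).
#' @export
potato_balance_schemes <- function() {
  list(
    texture = balance_scheme(
      "texture", c("sand", "silt", "clay", "C"),
      list(list(den = c("sand", "silt", "clay"), num = "C"),
           list(den = "clay", num = c("sand", "silt")),
           list(den = "silt", num = "sand"))),
    chem_p = balance_scheme(
      "chem_p", c("Fv", "Al", "P"),
      list(list(den = "Fv", num = c("Al", "P")),
           list(den = "Al", num = "P"))),
    chem_k = balance_scheme(
      "chem_k", c("Fv", "Mg", "Ca", "K"),
      list(list(den = c("Fv", "Mg", "Ca"), num = "K"),
           list(den = "Fv", num = c("Mg", "Ca")),
           list(den = "Mg", num = "Ca"))),
    soil_type = balance_scheme(
      "soil_type", c("loamy_gleyed", "sandy_gleyed", "podzolized"),
      list(list(den = c("loamy_gleyed", "sandy_gleyed"), num = "podzolized"),
           list(den = "loamy_gleyed", num = "sandy_gleyed"))),
    tuber_size = balance_scheme(
      "tuber_size", c("S", "M", "L"),
      list(list(den = c("M", "S"), num = "L"),
           list(den = "S", num = "M")))
  )
}

#' Isometric log-ratio transform of a composition
#'
#' @param composition Numeric vector of length D, or matrix/data.frame with D
#'   columns (one row per observation). All parts strictly positive; zeros
#'   must be imputed first (see [impute_size_zeros()]). Columns may be named
#'   as in `scheme$parts` (any order) or unnamed in scheme order.
#' @param scheme A [balance_scheme()].
#' @return Matrix of D-1 balances (columns labelled by contrast); the
#'   transform is invariant to multiplying a row by any positive constant.
#' @export
ilr_transform <- function(composition, scheme) {
  stopifnot(inherits(scheme, "balance_scheme"))
  x <- as.matrix(composition)
  if (is.vector(composition)) x <- matrix(composition, nrow = 1)
  D <- length(scheme$parts)
  if (ncol(x) != D) stop("composition must have ", D, " parts")
  if (!is.null(colnames(x)) && all(scheme$parts %in% colnames(x))) {
    x <- x[, scheme$parts, drop = FALSE]
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all parts must be strictly positive; ",
         "impute zeros first (impute_size_zeros)")
  }
  b <- log(x) %*% t(scheme$psi)
  colnames(b) <- scheme$labels
  b
}

#' Inverse isometric log-ratio transform
#'
#' Recovers the composition (closed to `total`) from balance coordinates;
#' `ilr_transform(ilr_inverse(b))` round-trips to machine precision.
#'
#' @param balances Numeric vector of length D-1 or matrix with D-1 columns.
#' @param scheme A [balance_scheme()].
#' @param total Closure constant (1 for proportions, 100 for percentages).
#' @return Matrix of compositions with parts as columns, rows summing
#'   to `total`.
#' @export
ilr_inverse <- function(balances, scheme, total = 1) {
  stopifnot(inherits(scheme, "balance_scheme"), total > 0)
  b <- as.matrix(balances)
  if (is.vector(balances)) b <- matrix(balances, nrow = 1)
  if (ncol(b) != length(scheme$parts) - 1) {
    stop("expected ", length(scheme$parts) - 1, " balances, got ", ncol(b))
  }
  lx <- b %*% scheme$psi
  x <- exp(lx)
  x <- x / rowSums(x) * total
  colnames(x) <- scheme$parts
  x
}

#' Impute zeros in tuber size-fraction compositions
#'
#' Log-ratio coordinates are undefined when a part is exactly zero (commonly
#' the large-size fraction on plots that produced no large tubers). Zeros are
#' replaced below a detection limit by multiplicative simple replacement:
#' each zero part of a row receives
#' \eqn{\delta = } `detection_limit` \eqn{\times} (smallest observed nonzero
#' value of that part across rows), and the remaining parts of the row are
#' shrunk by the factor \eqn{1 - \sum \delta} so the row re-closes to 1.
#'
#' @param fractions Matrix or data.frame of compositions closed to 1 (rows =
#'   plots, columns = parts, e.g. S, M, L).
#' @param detection_limit Fraction of the smallest observed nonzero part value
#'   used as replacement (default 0.65).
#' @return Matrix of strictly positive compositions closed to 1.
#' @export
impute_size_zeros <- function(fractions, detection_limit = 0.65) {
  x <- as.matrix(fractions)
  stopifnot(is.numeric(x), detection_limit > 0, detection_limit < 1)
  if (any(x < 0, na.rm = TRUE)) stop("fractions must be non-negative")
  if (any(rowSums(x) == 0)) stop("row with all parts zero cannot be imputed")
  delta <- apply(x, 2, function(col) {
    nz <- col[col > 0]
    if (length(nz) == 0) stop("a part is zero in every row; cannot set its detection limit")
    detection_limit * min(nz)
  })
  out <- x
  zero_rows <- which(rowSums(x == 0) > 0)
  for (i in zero_rows) {
    z <- x[i, ] == 0
    repl_total <- sum(delta[z])
    out[i, !z] <- x[i, !z] * (1 - repl_total)
    out[i, z] <- delta[z]
  }
  out
}
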