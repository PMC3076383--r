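#' @title Two-variable integer Laurent polynomials
#'
#' @description
#' The HOMFLY polynomial lives in the ring of Laurent polynomials with
#' integer coefficients in two variables, written `l` and `m` here.  A
#' `laurent2` object stores the finitely many nonzero terms as parallel
#' vectors of exponents and coefficients, kept in a canonical order
#' (sorted by the `l` exponent, then the `m` exponent) with no zero
#' coefficients, so that two polynomials are equal exactly when their
#' stored representations are identical.
#'
#' Arithmetic is exact: coefficients are stored as doubles but only ever
#' hold integers (the skein recursion multiplies and adds integer
#' monomial coefficients), and all operations re-canonicalise.
#'
#' @name laurent2
NULL

new_laurent2 <- function(el, em, coef) {
  stopifnot(length(el) == length(em), length(em) == length(coef))
  keep <- coef != 0
  el <- as.integer(el[keep]); em <- as.integer(em[keep]); coef <- coef[keep]
  if (length(el) > 1L) {
    # collapse duplicate exponent pairs, then sort canonically
    key <- paste(el, em)
    if (anyDuplicated(key)) {
      coef <- rowsum(coef, key)
      uk <- rownames(coef)
      coef <- as.vector(coef)
      parts <- strsplit(uk, " ", fixed = TRUE)
      el <- as.integer(vapply(parts, `[[`, "", 1L))
      em <- as.integer(vapply(parts, `[[`, "", 2L))
      keep <- coef != 0
      el <- el[keep]; em <- em[keep]; coef <- coef[keep]
    }
    o <- order(el, em)
    el <- el[o]; em <- em[o]; coef <- coef[o]
  }
  structure(list(el = el, em = em, coef = coef), class = "laurent2")
}

#' Construct a two-variable Laurent polynomial from terms
#'
#' @param el,em integer exponent vectors of the `l` and `m` variables.
#' @param coef integer coefficient vector, parallel to `el`/`em`.
#' @return a `laurent2` object in canonical form.
#' @examples
#' l2_poly(c(1, -1), c(-1, -1), c(-1, -1))  # -(l + 1/l)/m, the unlink factor
#' @export
l2_poly <- function(el, em, coef) new_laurent2(el, em, coef)

#' @rdname l2_poly
#' @export
l2_zero <- function() new_laurent2(integer(0), integer(0), numeric(0))

#' @rdname l2_poly
#' @export
l2_one <- function() new_laurent2(0L, 0L, 1)

#' @param a,b exponents of `l` and `m` for a single monomial.
#' @param c coefficient of the monomial.
#' @rdname l2_poly
#' @export
l2_mono <- function(c = 1, a = 0L, b = 0L) new_laurent2(a, b, c)

is_laurent2 <- function(x) inherits(x, "laurent2")

#' Arithmetic on two-variable Laurent polynomials
#'
#' Exact addition, negation and multiplication in the Laurent ring.
#'
#' @param p,q `laurent2` operands.
#' @return a `laurent2` object.
#' @export
l2_add <- function(p, q) {
  new_laurent2(c(p$el, q$el), c(p$em, q$em), c(p$coef, q$coef))
}

#' @rdname l2_add
#' @export
l2_neg <- function(p) new_laurent2(p$el, p$em, -p$coef)

#' @rdname l2_add
#' @export
l2_sub <- function(p, q) l2_add(p, l2_neg(q))

#' @rdname l2_add
#' @export
l2_mul <- function(p, q) {
  np <- length(p$coef); nq <- length(q$coef)
  if (np == 0L || nq == 0L) return(l2_zero())
  el <- rep(p$el, each = nq) + rep(q$el, times = np)
  em <- rep(p$em, each = nq) + rep(q$em, times = np)
  coef <- rep(p$coef, each = nq) * rep(q$coef, times = np)
  new_laurent2(el, em, coef)
}

#' @param n nonnegative integer power.
#' @rdname l2_add
#' @export
l2_pow <- function(p, n) {
  stopifnot(n >= 0, n == round(n))
  out <- l2_one()
  for (i in seq_len(n)) out <- l2_mul(out, p)
  out
}

#' @rdname l2_add
#' @export
l2_equal <- function(p, q) {
  identical(p$el, q$el) && identical(p$em, q$em) &&
    isTRUE(all.equal(p$coef, q$coef, tolerance = 0))
}

#' @rdname l2_add
#' @export
l2_is_zero <- function(p) length(p$coef) == 0L

#' Swap l and 1/l (mirror-image symmetry of HOMFLY)
#'
#' The HOMFLY polynomial of the mirror image of a link is obtained from
#' the original by substituting `l -> 1/l`.
#'
#' @param p a `laurent2` polynomial.
#' @return `p` with every `l` exponent negated.
#' @export
l2_mirror <- function(p) new_laurent2(-p$el, p$em, p$coef)

#' Canonical text form of a polynomial
#'
#' Terms are printed in canonical order as `c*l^a*m^b` joined with
#' explicit signs, e.g. `"-1*l^-4 + 1*l^-2*m^2 - 2*l^-2"`.  The zero
#' polynomial prints as `"0"` and the unit as `"1"`.
#'
#' @param p a `laurent2` polynomial.
#' @return a single string; parseable back with [l2_parse()].
#' @export
l2_format <- function(p) {
  if (length(p$coef) == 0L) return("0")
  term <- function(c, a, b) {
    parts <- as.character(abs(c))
    if (a != 0L) parts <- c(parts, sprintf("l^%d", a))
    if (b != 0L) parts <- c(parts, sprintf("m^%d", b))
    paste(parts, collapse = "*")
  }
  # print highest l-degree first for readability
  o <- order(-p$el, -p$em)
  el <- p$el[o]; em <- p$em[o]; coef <- p$coef[o]
  out <- term(coef[1], el[1], em[1])
  if (coef[1] < 0) out <- paste0("-", out)
  for (i in seq_along(coef)[-1]) {
    sign <- if (coef[i] < 0) " - " else " + "
    out <- paste0(out, sign, term(coef[i], el[i], em[i]))
  }
  out
}

#' @rdname l2_format
#' @param text a string as produced by [l2_format()].
#' @export
l2_parse <- function(text) {
  text <- gsub("\\s+", "", text)
  if (text == "0") return(l2_zero())
  text <- gsub("^-", "~", gsub("\\^-", "^~", text))  # protect exponent signs
  text <- gsub("-", "+-", text, fixed = TRUE)
  text <- gsub("~", "-", text, fixed = TRUE)
  terms <- strsplit(text, "+", fixed = TRUE)[[1]]
  terms <- terms[nzchar(terms)]
  el <- integer(0); em <- integer(0); coef <- numeric(0)
  for (t in terms) {
    factors <- strsplit(t, "*", fixed = TRUE)[[1]]
    c_i <- 1; a_i <- 0L; b_i <- 0L
    for (f in factors) {
      if (grepl("^l\\^", f)) a_i <- as.integer(sub("^l\\^", "", f))
      else if (f == "l") a_i <- 1L
      else if (grepl("^m\\^", f)) b_i <- as.integer(sub("^m\\^", "", f))
      else if (f == "m") b_i <- 1L
      else if (f == "-") c_i <- -c_i
      else c_i <- c_i * as.numeric(f)
    }
    el <- c(el, a_i); em <- c(em, b_i); coef <- c(coef, c_i)
  }
  new_laurent2(el, em, coef)
}

#' @export
print.laurent2 <- function(x, ...) {
  cat("<laurent2> ", l2_format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.laurent2 <- function(x, ...) l2_format(x)

# fixed skein coefficients of the convention used throughout:
#   l * P(L+) + (1/l) * P(L-) + m * P(L0) = 0,   P(unknot) = 1
skein_delta <- function() l2_poly(c(1L, -1L), c(-1L, -1L), c(-1, -1))

#' Polynomial of the k-component unlink
#'
#' In the convention `l*P(L+) + l^-1*P(L-) + m*P(L0) = 0` with
#' `P(unknot) = 1`, the k-component unlink has polynomial
#' `delta^(k-1)` where `delta = -(l + l^-1)/m`.
#'
#' @param k number of components, `k >= 1`.
#' @return a `laurent2` polynomial.
#' @examples
#' unlink_poly(1)  # 1
#' unlink_poly(2)  # -(l + l^-1) * m^-1
#' @export
unlink_poly <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a positive integer component count")
  l2_pow(skein_delta(), k - 1)
}

#' Evaluate a polynomial numerically (complex arguments allowed)
#'
#' Used internally for specialization sanity checks.
#' @param p a `laurent2` polynomial.
#' @param l,m complex values substituted for the two variables.
#' @return a complex number.
#' @export
l2_eval <- function(p, l, m) {
  if (length(p$coef) == 0L) return(0 + 0i)
  sum(p$coef * l^p$el * m^p$em)
}
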