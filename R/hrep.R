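#' H-representation of a polytope
#'
#' An `hrep` holds the system \eqn{Ax \le b}: `m` half-spaces
#' \eqn{H_i = \{x : a_i \cdot x \le b_i\}} in dimension `n`, with all entries
#' exact rationals.  Rows are indexed `0, ..., m-1`; the feasible region is
#' assumed bounded and full-dimensional, which requires `m > n`.
#'
#' @param A an `m x n` matrix of constraint vectors \eqn{a_i} as rows;
#'   numeric (integral / binary-fraction values) or character rationals.
#' @param b length-`m` right-hand side.
#' @return an object of class `hrep` with fields `A`, `b` (canonical rational
#'   character matrix / vector), `m` and `n`.
#' @examples
#' # the unit segment 0 <= x <= 1
#' H <- hrep(rbind(1, -1), c(1, 0))
#' H
#' @export
hrep <- function(A, b) {
  if (!is.matrix(A)) A <- as.matrix(A)
  Ac <- as_rational(A)
  bc <- as_rational(b)
  m <- nrow(Ac)
  n <- ncol(Ac)
  if (length(bc) != m)
    stop("b has length ", length(bc), " but A has ", m, " rows")
  if (m <= n)
    stop("need m > n (got m = ", m, ", n = ", n, "): a bounded ",
         "full-dimensional polytope requires more half-spaces than ",
         "dimensions")
  structure(list(A = Ac, b = bc, m = m, n = n), class = "hrep")
}

#' @export
print.hrep <- function(x, ...) {
  cat("H-representation: m =", x$m, "half-spaces in dimension n =", x$n, "\n")
  k <- min(x$m, 6L)
  for (i in seq_len(k))
    cat(sprintf("  [%2d]  a = (%s)  b = %s\n", i - 1L,
                paste(x$A[i, ], collapse = ", "), x$b[i]))
  if (x$m > k) cat("  ... ", x$m - k, "more rows\n")
  invisible(x)
}

#' @export
format.hrep <- function(x, ...) {
  sprintf("<hrep: m=%d, n=%d>", x$m, x$n)
}

stopifnot_hrep <- function(H) {
  if (!inherits(H, "hrep")) stop("expected an 'hrep' object")
  invisible(H)
}

# validate and canonicalize a point in ambient coordinates
as_point <- function(H, p) {
  p <- as_rational(p)
  if (length(p) != H$n)
    stop("point has length ", length(p), " but the system has dimension ",
         H$n)
  p
}

#' Read an H-representation from a cdd-style `.ine` file
#'
#' The dialect understood is: optional comment lines (starting with `*` or
#' `#`, or any text before the `H-representation` keyword), the line
#' `H-representation`, `begin`, a header `m n+1 <numbertype>`, then `m` rows
#' of `n+1` whitespace-separated fields storing \eqn{(b_i, -a_i)} -- i.e. row
#' \eqn{i} encodes \eqn{b_i - a_i \cdot x \ge 0} -- and finally `end`.
#' Numbers may be integers, `p/q` rationals or decimal literals; all are
#' ingested exactly.  `linearity` (equality) blocks are not supported and
#' raise an error.
#'
#' @param path file path.
#' @return an [hrep()].
#' @seealso [write_hrep()] for the emitted dialect; the round trip is the
#'   identity.
#' @export
read_hrep <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  is_comment <- startsWith(lines, "*") | startsWith(lines, "#")
  hdr <- which(tolower(lines) == "h-representation" & !is_comment)
  if (length(hdr) == 0L)
    stop("not an .ine file: no 'H-representation' line in ", path)
  hdr <- hdr[1L]
  rest <- lines[(hdr + 1L):length(lines)]
  rest <- rest[nzchar(rest)]
  rest <- rest[!(startsWith(rest, "*") | startsWith(rest, "#"))]
  if (any(grepl("^linearity", tolower(rest))))
    stop("equality ('linearity') blocks are not supported; ",
         "only pure inequality systems can be read")
  if (tolower(rest[1L]) != "begin")
    stop("malformed .ine file: expected 'begin' after 'H-representation' ",
         "(line ", hdr + 1L, ")")
  size <- strsplit(rest[2L], "\\s+")[[1L]]
  if (length(size) < 2L)
    stop("malformed .ine header on line ", hdr + 2L,
         ": expected 'm n+1 numbertype'")
  m <- suppressWarnings(as.integer(size[1L]))
  d <- suppressWarnings(as.integer(size[2L]))
  if (is.na(m) || is.na(d))
    stop("malformed .ine header on line ", hdr + 2L,
         ": non-integer dimensions")
  body <- rest[-(1:2)]
  endl <- which(tolower(body) == "end")
  if (length(endl) == 0L) stop("malformed .ine file: missing 'end'")
  body <- body[seq_len(endl[1L] - 1L)]
  if (length(body) != m)
    stop("declared m = ", m, " rows but found ", length(body),
         " data rows before 'end'")
  n <- d - 1L
  A <- matrix("0", m, n)
  b <- character(m)
  for (i in seq_len(m)) {
    tok <- strsplit(body[i], "\\s+")[[1L]]
    tok <- tok[nzchar(tok)]
    if (length(tok) != d)
      stop("row ", i, " has ", length(tok), " fields, expected ", d)
    row <- tryCatch(as_rational(tok),
                    error = function(e)
                      stop("non-numeric token in data row ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    b[i] <- row[1L]
    # stored as (b_i, -a_i); negate to recover a_i
    A[i, ] <- vapply(row[-1L], q_negate, character(1L))
  }
  hrep(A, b)
}

# negate a canonical rational string without arithmetic round trips
q_negate <- function(s) {
  if (s == "0") "0"
  else if (startsWith(s, "-")) substring(s, 2L)
  else paste0("-", s)
}

#' Write an H-representation to a cdd-style `.ine` file
#'
#' Emits exactly the dialect read by [read_hrep()], storing each row as
#' \eqn{(b_i, -a_i)}.  Rational entries are written as `p/q`, so the
#' round trip `read_hrep(write_hrep(H))` reproduces `H` entrywise.
#'
#' @param H an [hrep()].
#' @param path output file path.
#' @param name optional comment written at the top of the file.
#' @return `path`, invisibly.
#' @export
write_hrep <- function(H, path, name = NULL) {
  stopifnot_hrep(H)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name)) writeLines(paste("*", name), con)
  writeLines("H-representation", con)
  writeLines("begin", con)
  writeLines(paste(H$m, H$n + 1L, "rational"), con)
  for (i in seq_len(H$m)) {
    row <- c(H$b[i], vapply(H$A[i, ], q_negate, character(1L)))
    writeLines(paste(row, collapse = " "), con)
  }
  writeLines("end", con)
  invisible(path)
}
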