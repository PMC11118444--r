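#' Construct a pedigree
#'
#' A pedigree is a table of individuals with, for each non-founder, its two
#' (possibly identical) recorded parents.  Founders carry no parent
#' records and are treated as non-inbred and mutually unrelated, the usual
#' base-population convention of herd-book analyses.
#'
#' @param id Character or integer vector of individual identifiers
#'   (unique).
#' @param sire,dam Parent identifiers aligned with `id`; use `NA`, `"0"`
#'   or `"."` for unknown.  A non-founder must have both parents recorded.
#' @return A tibble of class `pedigree` with character columns `id`,
#'   `sire`, `dam` (`NA` for founders), topologically ordered so parents
#'   precede offspring.
#' @examples
#' ped <- pedigree(
#'   id = c("A", "B", "C", "D"),
#'   sire = c(NA, NA, "A", "A"),
#'   dam = c(NA, NA, "B", "C")
#' )
#' inbreeding_coef(ped, "D")
#' @export
pedigree <- function(id, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", ".", "")] <- NA_character_
    x
  }
  id <- as.character(id)
  sire <- norm(sire)
  dam <- norm(dam)
  if (anyDuplicated(id)) abort("duplicated individual identifiers in pedigree.")
  if (length(sire) != length(id) || length(dam) != length(id)) {
    abort("`id`, `sire` and `dam` must have the same length.")
  }
  if (any(xor(is.na(sire), is.na(dam)))) {
    abort("each non-founder needs both parents recorded (or neither, for a founder).")
  }
  known <- c(sire, dam)
  missing_parents <- setdiff(known[!is.na(known)], id)
  if (length(missing_parents)) {
    abort(sprintf(
      "parent(s) not present as individuals: %s",
      paste(missing_parents, collapse = ", ")
    ))
  }
  ped <- tibble::tibble(id = id, sire = sire, dam = dam)
  ord <- topo_order(ped)                     # errors on cycles
  ped <- ped[ord, ]
  class(ped) <- c("pedigree", class(ped))
  ped
}

## Kahn topological sort; detects cycles.
topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        children[[j]] <- c(children[[j]], i)
        indeg[i] <- indeg[i] + 1L
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != n) abort("pedigree contains a cycle.")
  out
}

#' Read a pedigree from a delimited file
#'
#' Expects three columns (id, sire, dam) with one header line; `0` or `.`
#' mark unknown parents.  Whitespace- or tab-delimited.
#'
#' @param path Path to the pedigree file.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = TRUE, colClasses = "character")
  if (ncol(tab) < 3) abort("pedigree file must have columns id, sire, dam.")
  pedigree(tab[[1]], tab[[2]], tab[[3]])
}

#' Kinship and inbreeding coefficients on a pedigree
#'
#' `kinship_coef()` computes the kinship (coancestry) coefficient
#' \eqn{\varphi(a, b)} — the probability that one gene drawn at random
#' from `a` and one from `b` are identical by descent relative to the
#' pedigree founders — by the standard recursion
#' \eqn{\varphi(a, a) = (1 + F_a)/2} and
#' \eqn{\varphi(a, b) = [\varphi(\mathrm{sire}_b, a) +
#' \varphi(\mathrm{dam}_b, a)]/2},
#' with distinct founders unrelated.  `inbreeding_coef()` returns
#' \eqn{F_x = \varphi(\mathrm{sire}_x, \mathrm{dam}_x)} (0 for founders).
#'
#' @param ped A [pedigree].
#' @param a,b Individual identifiers.
#' @return A single numeric coefficient.
#' @examples
#' # offspring of a parent x own-offspring mating
#' ped <- pedigree(c("P", "Q", "X", "Z"), c(NA, NA, "P", "P"),
#'                 c(NA, NA, "Q", "X"))
#' inbreeding_coef(ped, "Z")  # 0.25
#' @export
kinship_coef <- function(ped, a, b) {
  stopifnot(inherits(ped, "pedigree"))
  for (x in c(a, b)) {
    if (!x %in% ped$id) abort(sprintf("unknown individual '%s'.", x))
  }
  env <- kinship_env(ped)
  phi(env, a, b)
}

#' @rdname kinship_coef
#' @param individual Identifier of the individual whose inbreeding
#'   coefficient is required.
#' @export
inbreeding_coef <- function(ped, individual) {
  stopifnot(inherits(ped, "pedigree"))
  if (!individual %in% ped$id) {
    abort(sprintf("unknown individual '%s'.", individual))
  }
  i <- match(individual, ped$id)
  if (is.na(ped$sire[i])) return(0)
  kinship_coef(ped, ped$sire[i], ped$dam[i])
}

kinship_env <- function(ped) {
  env <- new.env(parent = emptyenv())
  env$sire <- setNames(ped$sire, ped$id)
  env$dam <- setNames(ped$dam, ped$id)
  env$memo <- new.env(parent = emptyenv())
  env
}

phi <- function(env, a, b) {
  key <- paste(sort(c(a, b)), collapse = "\r")
  hit <- env$memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (a == b) {
    sa <- env$sire[[a]]
    (1 + if (is.na(sa)) 0 else phi(env, sa, env$dam[[a]])) / 2
  } else {
    ## recurse through the individual that appears later in the
    ## topological order, so parents are always defined before use
    ia <- match(a, names(env$sire))
    ib <- match(b, names(env$sire))
    if (ia > ib) { tmp <- a; a <- b; b <- tmp }
    sb <- env$sire[[b]]
    if (is.na(sb)) 0 else (phi(env, sb, a) + phi(env, env$dam[[b]], a)) / 2
  }
  assign(key, val, envir = env$memo)
  val
}
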