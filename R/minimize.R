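#' Exact two-level minimization of a truth table
#'
#' Computes a minimal sum-of-products expression for a (possibly partial)
#' truth table by the Quine-McCluskey procedure: all prime implicants are
#' enumerated over the union of the on-set and the don't-care set, and an
#' exact minimum cover of the on-set is then found by essential-implicant
#' reduction followed by branch-and-bound search.  This is the programmatic
#' equivalent of grouping ones (and don't-cares) in powers of two on a
#' Karnaugh map.  Ties are broken by fewest product terms, then fewest
#' total literals, then lexicographic order of the term strings.
#'
#' @param values vector of length `2^k` over `{0, 1, NA}` (`NA` =
#'   don't-care), indexed by the predictor assignment read as a binary
#'   number with the first variable as the most significant bit (so
#'   `values[1]` is the all-zero cell).
#' @param vars character vector of the `k` variable names (k <= 6).
#' @return A `bn_expr` in sum-of-products form (an `or` of `and` terms,
#'   single literals, or a constant), with attribute `"terms"`: a character
#'   matrix, one row per product term over `{"0","1","-"}`.
#' @examples
#' # Nrf2' table of the oxidative stress fixture: PKC | !Keap1
#' minimize_sop(c(1, 0, 1, 1), c("PKC", "Keap1"))
#' @export
minimize_sop <- function(values, vars) {
  k <- length(vars)
  stopifnot(k >= 0L, k <= 6L, length(values) == 2^k)
  values <- as.integer(values)
  on <- which(values == 1L) - 1L
  dc <- which(is.na(values)) - 1L
  off <- which(values == 0L) - 1L

  if (length(on) == 0L) return(with_terms(bx_const(0L), matrix("", 0, k)))
  if (length(off) == 0L)
    return(with_terms(bx_const(1L), matrix("-", 1, k,
                                           dimnames = list(NULL, vars))))

  primes <- prime_implicants(c(on, dc), k)
  # keep primes covering at least one on-set minterm
  cover <- lapply(primes, function(p) intersect(implicant_cells(p, k), on))
  keep <- lengths(cover) > 0L
  primes <- primes[keep]; cover <- cover[keep]
  # deterministic order: lexicographic by term string
  strs <- vapply(primes, implicant_string, "", k = k)
  o <- order(strs)
  primes <- primes[o]; cover <- cover[o]; strs <- strs[o]

  sel <- min_cover(cover, on, n_lit = vapply(primes, function(p) sum(p$mask), 0L))
  terms <- do.call(rbind, lapply(primes[sel], function(p)
    implicant_chars(p, k)))
  colnames(terms) <- vars
  terms <- terms[order(apply(terms, 1L, paste, collapse = "")), , drop = FALSE]
  with_terms(terms_to_expr(terms, vars), terms)
}

with_terms <- function(expr, terms) {
  attr(expr, "terms") <- terms
  expr
}

# implicant: list(mask = logical k-vector of fixed positions (MSB first),
#                 bits = integer k-vector, meaningful where mask is TRUE)
implicant_cells <- function(p, k) {
  free <- which(!p$mask)
  base <- sum(p$bits[p$mask] * 2^(k - which(p$mask)))
  if (length(free) == 0L) return(base)
  combos <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  as.integer(base + combos %*% 2^(k - free))
}

implicant_chars <- function(p, k) {
  ch <- rep("-", k)
  ch[p$mask] <- as.character(p$bits[p$mask])
  ch
}

implicant_string <- function(p, k) paste(implicant_chars(p, k), collapse = "")

prime_implicants <- function(minterms, k) {
  if (k == 0L) return(list(list(mask = logical(0), bits = integer(0))))
  minterms <- sort(unique(as.integer(minterms)))
  bits_of <- function(d) as.integer(bitwAnd(bitwShiftR(d, (k - 1L):0), 1L))
  current <- lapply(minterms, function(d)
    list(mask = rep(TRUE, k), bits = bits_of(d)))
  primes <- list()
  repeat {
    n <- length(current)
    merged <- rep(FALSE, n)
    nxt <- list()
    seen <- character(0)
    key <- function(p) paste(implicant_string(p, k), collapse = "")
    if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      a <- current[[i]]; b <- current[[j]]
      if (!identical(a$mask, b$mask)) next
      diffpos <- which(a$mask & (a$bits != b$bits))
      if (length(diffpos) != 1L) next
      m <- a
      m$mask[diffpos] <- FALSE
      m$bits[diffpos] <- 0L
      merged[i] <- merged[j] <- TRUE
      kk <- key(m)
      if (!(kk %in% seen)) { seen <- c(seen, kk); nxt[[length(nxt) + 1L]] <- m }
    }
    primes <- c(primes, current[!merged])
    if (length(nxt) == 0L) break
    current <- nxt
  }
  # dedupe
  ks <- vapply(primes, implicant_string, "", k = k)
  primes[!duplicated(ks)]
}

# Exact minimum cover: essential reduction + branch and bound.
# cover: list, per candidate, of the on-set cells it covers.
# Returns indices of the chosen candidates (first-found among cost ties,
# which is lexicographic because candidates arrive sorted).
min_cover <- function(cover, on, n_lit) {
  chosen <- integer(0)
  uncovered <- on
  # essential implicants, applied to fixpoint
  repeat {
    if (length(uncovered) == 0L) break
    counts <- integer(length(uncovered))
    only <- integer(length(uncovered))
    for (i in seq_along(cover)) {
      hit <- match(cover[[i]], uncovered, nomatch = 0L)
      hit <- hit[hit > 0L]
      counts[hit] <- counts[hit] + 1L
      only[hit] <- i
    }
    ess <- unique(only[counts == 1L])
    ess <- setdiff(ess, chosen)
    if (length(ess) == 0L) break
    chosen <- c(chosen, ess)
    uncovered <- setdiff(uncovered, unlist(cover[ess]))
  }
  if (length(uncovered) == 0L) return(sort(chosen))

  cand <- which(vapply(cover, function(cc) any(cc %in% uncovered), TRUE))
  best <- NULL
  best_cost <- c(Inf, Inf)
  dfs <- function(sel, uncov) {
    cost <- c(length(sel), sum(n_lit[sel]))
    if (length(uncov) == 0L) {
      if (cost[1L] < best_cost[1L] ||
          (cost[1L] == best_cost[1L] && cost[2L] < best_cost[2L])) {
        best <<- sel; best_cost <<- cost
      }
      return(invisible(NULL))
    }
    # at least one more term is needed to finish
    if (cost[1L] + 1L > best_cost[1L]) return(invisible(NULL))
    # branch on the hardest cell (fewest covering candidates)
    nopt <- vapply(uncov, function(m)
      sum(vapply(cand, function(i) m %in% cover[[i]], TRUE)), 0L)
    cell <- uncov[which.min(nopt)]
    for (i in cand) {
      if (!(cell %in% cover[[i]]) || i %in% sel) next
      dfs(c(sel, i), setdiff(uncov, cover[[i]]))
    }
  }
  dfs(chosen, uncovered)
  sort(best)
}

terms_to_expr <- function(terms, vars) {
  term_expr <- function(row) {
    lits <- list()
    for (j in seq_along(vars)) {
      if (row[[j]] == "1") lits[[length(lits) + 1L]] <- bx_var(vars[[j]])
      else if (row[[j]] == "0") lits[[length(lits) + 1L]] <- bx_not(bx_var(vars[[j]]))
    }
    if (length(lits) == 0L) return(bx_const(1L))
    if (length(lits) == 1L) return(lits[[1L]])
    bx_and(lits)
  }
  exprs <- lapply(seq_len(nrow(terms)), function(i) term_expr(terms[i, ]))
  if (length(exprs) == 1L) exprs[[1L]] else bx_or(exprs)
}
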