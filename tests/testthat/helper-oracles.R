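# Independent brute-force oracles for the substructure engine and the
# coloring symmetry classes.  These deliberately share no code with the
# package: plain enumeration over heavy-atom views.

# heavy-atom view of a molecule as plain vectors/matrices
oracle_view <- function(mol, drop_r = FALSE) {
  keep <- which(mol$atoms$element != "H")
  if (drop_r) keep <- keep[!mol$atoms$is_r[keep]]
  idx <- match(seq_len(nrow(mol$atoms)), keep)
  n <- length(keep)
  adj <- matrix(NA_character_, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- idx[mol$bonds$a[k]]; b <- idx[mol$bonds$b[k]]
    if (is.na(a) || is.na(b)) next
    adj[a, b] <- adj[b, a] <- mol$bonds$order[k]
  }
  list(n = n, el = mol$atoms$element[keep], is_r = mol$atoms$is_r[keep],
       chg = mol$atoms$charge[keep], adj = adj, orig = keep)
}

oracle_label_ok <- function(pv, i, tv, j) {
  if (pv$is_r[i]) return(TRUE)
  pv$el[i] == tv$el[j]
}

oracle_order_ok <- function(po, to, strict) {
  if (!strict) return(TRUE)
  identical(po, to)
}

# all injective monomorphisms pattern -> target, as sorted strings
# "p1:t1,p2:t2,..."
oracle_embeddings <- function(pattern, target, ignore_r_h = FALSE,
                              order_strict = TRUE) {
  pv <- oracle_view(pattern, drop_r = ignore_r_h)
  tv <- oracle_view(target)
  res <- character(0)
  map <- integer(pv$n)
  recurse <- function(i) {
    if (i > pv$n) {
      key <- paste(sprintf("%d:%d", pv$orig, tv$orig[map]), collapse = ",")
      res <<- c(res, key)
      return()
    }
    for (j in seq_len(tv$n)) {
      if (j %in% map[seq_len(i - 1L)]) next
      if (!oracle_label_ok(pv, i, tv, j)) next
      ok <- TRUE
      for (k in seq_len(i - 1L)) {
        po <- pv$adj[i, k]
        if (!is.na(po)) {
          to <- tv$adj[j, map[k]]
          if (is.na(to) || !oracle_order_ok(po, to, order_strict)) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      map[i] <<- j
      recurse(i + 1L)
      map[i] <<- 0L
    }
  }
  if (pv$n > tv$n) return(character(0))
  recurse(1L)
  sort(res)
}

oracle_isomorphic <- function(a, b, order_strict = TRUE) {
  av <- oracle_view(a); bv <- oracle_view(b)
  if (av$n != bv$n) return(FALSE)
  if (sum(!is.na(av$adj)) != sum(!is.na(bv$adj))) return(FALSE)
  length(oracle_embeddings(a, b, order_strict = order_strict)) > 0L
}

# exhaustive maximum connected common subgraph: enumerate every injective
# partial map, require connectivity through matched bonds, return best
# (natoms, nbonds)
oracle_mcs_size <- function(a, b, order_strict = TRUE) {
  av <- oracle_view(a); bv <- oracle_view(b)
  best <- c(0L, 0L)
  map <- rep(NA_integer_, av$n)
  score <- function() {
    sel <- which(!is.na(map))
    k <- length(sel)
    if (k == 0L) return(invisible())
    nb <- 0L
    # matched-bond graph connectivity
    madj <- vector("list", k)
    for (x in seq_len(k)) madj[[x]] <- integer(0)
    for (x in seq_len(k)) for (y in seq_len(k)) {
      if (x >= y) next
      po <- av$adj[sel[x], sel[y]]
      if (is.na(po)) next
      to <- bv$adj[map[sel[x]], map[sel[y]]]
      if (is.na(to) || !oracle_order_ok(po, to, order_strict)) next
      nb <- nb + 1L
      madj[[x]] <- c(madj[[x]], y); madj[[y]] <- c(madj[[y]], x)
    }
    seen <- 1L; queue <- 1L
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      new <- setdiff(madj[[cur]], seen)
      seen <- c(seen, new); queue <- c(queue, new)
    }
    if (length(seen) != k) return(invisible())
    if (k > best[1L] || (k == best[1L] && nb > best[2L])) best <<- c(k, nb)
    invisible()
  }
  recurse <- function(i) {
    if (i > av$n) { score(); return() }
    recurse(i + 1L)  # leave i unmapped
    for (j in seq_len(bv$n)) {
      if (j %in% map) next
      if (!oracle_label_ok(av, i, bv, j)) next
      map[i] <<- j
      recurse(i + 1L)
      map[i] <<- NA_integer_
    }
  }
  recurse(1L)
  best
}

# automorphism orbits by permutation enumeration (n <= 8)
oracle_orbits <- function(mol) {
  v <- oracle_view(mol)
  n <- v$n
  perms <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (p in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
    }
    out
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (p in perms(seq_len(n))) {
    ok <- all(v$el[p] == v$el) && all(v$chg[p] == v$chg) && all(v$is_r[p] == v$is_r)
    if (ok) {
      for (x in seq_len(n)) {
        for (y in seq_len(n)) {
          po <- v$adj[x, y]; to <- v$adj[p[x], p[y]]
          if (!identical(po, to)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) {
      for (i in seq_len(n)) {
        ri <- find(i); rj <- find(p[i])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(v$orig, roots))
}

match_keys <- function(hits) {
  sort(vapply(hits, function(h) {
    paste(sprintf("%d:%d", h$mapping$pattern, h$mapping$target), collapse = ",")
  }, character(1)))
}
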