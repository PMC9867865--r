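#' @include AllClasses.R
NULL

# ---- count-set mini-language ----------------------------------------------
# a count specification is a single integer ("5"), a list ("[0,2,4,5]") or an
# inclusive range ("[0-5]"); list entries may themselves be ranges

.parseCountSet <- function(txt, pos = 1L) {
  txt <- trimws(txt)
  if (!nzchar(txt)) stop("empty count-set at position ", pos, call. = FALSE)
  if (grepl("^[0-9]+$", txt)) return(as.integer(txt))
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  vals <- integer(0)
  for (p in parts) {
    p <- trimws(p)
    if (grepl("^[0-9]+$", p)) {
      vals <- c(vals, as.integer(p))
    } else if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      if (ab[2] < ab[1]) stop("descending range '", p, "' at position ", pos,
                              call. = FALSE)
      vals <- c(vals, seq.int(ab[1], ab[2]))
    } else {
      stop("malformed count token '", p, "' at position ", pos, call. = FALSE)
    }
  }
  if (!length(vals)) stop("empty count-set at position ", pos, call. = FALSE)
  sort(unique(vals))
}

# ---- formula parsing -------------------------------------------------------

#' Parse a molecular formula string
#'
#' Understands element counts given as a single integer (\code{"H5"}), a list
#' (\code{"H[0,2,4,5]"}) or an inclusive range (\code{"H[0-5]"}), and
#' united-atom specifications with a pinned hydrogen count in braces
#' (\code{"\{CH1\}1\{CH2\}2\{OH1\}3"}).  A missing count means 1.
#'
#' @param text formula string, e.g. \code{"C[1-10]H[4-22]"}
#' @return a [MolecularFormula-class]
#' @examples
#' parseFormula("C4H10")
#' parseFormula("{CH1}1{CH2}2{OH1}3")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  n <- nchar(s)
  if (n == 0L) stop("empty formula", call. = FALSE)
  i <- 1L
  free <- list()
  fixed <- list()
  err <- function(msg, at) stop("formula parse error at position ", at, ": ",
                                msg, call. = FALSE)
  readSymbol <- function() {
    # longest match against the element table (two-letter symbols first)
    for (len in c(2L, 1L)) {
      cand <- substr(s, i, i + len - 1L)
      if (cand %in% .ELEMENTS$symbol) {
        i <<- i + len
        return(cand)
      }
    }
    err(paste0("unknown element at '", substr(s, i, min(n, i + 2L)), "'"), i)
  }
  readCount <- function() {
    if (i > n) return(1L)
    ch <- substr(s, i, i)
    if (grepl("^[0-9]$", ch)) {
      j <- i
      while (j <= n && grepl("^[0-9]$", substr(s, j, j))) j <- j + 1L
      v <- as.integer(substr(s, i, j - 1L))
      i <<- j
      return(v)
    }
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) err("unterminated '['", i)
      inner <- substr(s, i + 1L, i + j - 2L)
      v <- .parseCountSet(inner, i)
      i <<- i + j
      return(v)
    }
    1L
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "{") {
      open <- i
      close <- regexpr("}", substr(s, i, n), fixed = TRUE)
      if (close < 0) err("unterminated '{'", open)
      inner <- substr(s, i + 1L, i + close - 2L)
      m <- regmatches(inner, regexec("^([A-Z][a-z]?)H([0-9]+)$", inner))[[1]]
      if (length(m) != 3L)
        err(paste0("malformed united-atom spec '{", inner, "}'"), open)
      sym <- m[2]
      nH <- as.integer(m[3])
      if (!sym %in% .ELEMENTS$symbol) err(paste0("unknown element '", sym, "'"), open)
      val <- .elementValence(sym)
      if (nH > val)
        err(paste0("implicit hydrogen count ", nH, " exceeds valence of ", sym), open)
      i <- i + close
      cnt <- readCount()
      fixed[[length(fixed) + 1L]] <- list(symbol = sym, nH = nH, counts = cnt)
    } else if (grepl("^[A-Z]$", ch)) {
      at <- i
      sym <- readSymbol()
      cnt <- readCount()
      if (!is.null(free[[sym]]))
        err(paste0("element '", sym, "' specified twice"), at)
      free[[sym]] <- cnt
    } else {
      err(paste0("unexpected character '", ch, "'"), i)
    }
  }
  fx <- if (length(fixed)) {
    data.frame(symbol = vapply(fixed, `[[`, "", "symbol"),
               nH = vapply(fixed, `[[`, 0L, "nH"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(symbol = character(0), nH = integer(0))
  }
  fx$counts <- lapply(fixed, `[[`, "counts")
  new("MolecularFormula", free = free, fixed = fx, text = text)
}

# ---- expansion to concrete formulas ---------------------------------------

.hillLabel <- function(counts) {
  counts <- counts[counts > 0]
  syms <- names(counts)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Expand a formula into concrete formulas
#'
#' Enumerates the cross product of all element count-sets, dropping
#' chemically impossible combinations (no atoms, odd total valence, negative
#' unsaturation count).
#'
#' @param formula a [MolecularFormula-class] or formula string
#' @return list of concrete formulas; each has elements \code{counts} (named
#'   totals including hydrogen), \code{free} (free element counts),
#'   \code{fixed} (united-atom constraints with integer counts) and
#'   \code{label}
#' @export
expandFormula <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  stopifnot(is(formula, "MolecularFormula"))
  freeSets <- formula@free
  fixedSets <- formula@fixed$counts
  grid <- c(freeSets, fixedSets)
  if (!length(grid)) return(list())
  combos <- do.call(expand.grid, c(lapply(grid, as.integer),
                                   list(KEEP.OUT.ATTRS = FALSE)))
  nFree <- length(freeSets)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    freeC <- setNames(as.integer(combos[r, seq_len(nFree)]), names(freeSets))
    fixedC <- if (length(fixedSets))
      as.integer(combos[r, nFree + seq_along(fixedSets)]) else integer(0)
    fx <- formula@fixed[, c("symbol", "nH")]
    fx$count <- fixedC
    fx <- fx[fx$count > 0, , drop = FALSE]
    # total element counts including hydrogens carried by fixed specs
    counts <- freeC[freeC > 0]
    for (k in seq_len(nrow(fx))) {
      sym <- fx$symbol[k]
      counts[sym] <- (if (is.na(counts[sym])) 0L else counts[sym]) + fx$count[k]
      hAdd <- fx$count[k] * fx$nH[k]
      counts["H"] <- (if (is.na(counts["H"])) 0L else counts["H"]) + hAdd
    }
    counts <- counts[!is.na(counts) & counts > 0]
    names(counts) <- sub("\\.*$", "", names(counts))
    if (!length(counts)) next
    vals <- .elementValence(names(counts))
    if (sum(counts * vals) %% 2L != 0L) next
    u <- (2 + sum(counts * (vals - 2L))) / 2
    if (u < 0) next
    out[[length(out) + 1L]] <- list(counts = counts, free = freeC, fixed = fx,
                                    label = .hillLabel(counts))
  }
  out
}

#' Number of unsaturations of a molecular formula
#'
#' Degree of unsaturation from the fixed element valences: double bonds and
#' cycles each count one, triple bonds count two.  For element counts
#' \eqn{n_e} with valences \eqn{\delta_e} the count is
#' \eqn{(2 + \sum_e n_e(\delta_e - 2))/2}.
#'
#' @param x a named integer vector of element counts (names are element
#'   symbols), a concrete formula from [expandFormula()], or a formula string
#'   that expands to a single concrete formula
#' @return the (possibly negative) unsaturation count; negative means the
#'   formula admits no isomer
#' @examples
#' unsaturations(c(C = 1, H = 4))  # 0
#' unsaturations("C2H4")           # 1
#' @export
unsaturations <- function(x) {
  if (is.character(x)) {
    cf <- expandFormula(x)
    if (length(cf) != 1L)
      stop("formula does not expand to a single concrete formula")
    x <- cf[[1]]$counts
  } else if (is.list(x) && !is.null(x$counts)) {
    x <- x$counts
  }
  stopifnot(is.numeric(x), !is.null(names(x)))
  vals <- .elementValence(names(x))
  tot <- sum(x * vals)
  if (tot %% 2 != 0) stop("odd total valence: not a valid molecular formula")
  (2 + sum(x * (vals - 2))) / 2
}

# ---- hydrogen distribution -------------------------------------------------

# canonical ordering of united-atom types: decreasing effective valence,
# ties by element symbol, then decreasing implicit-hydrogen count
.orderTypes <- function(df) {
  df[order(-df$effValence, df$symbol, -df$nH), , drop = FALSE]
}

#' Distribute hydrogens over the heavy atoms
#'
#' Enumerates every way of associating the hydrogen atoms of a concrete
#' formula with its heavy atoms, producing united-atom partitions (multisets
#' of element + attached-H count).  United atoms pinned by a
#' \code{\{CH1\}}-style spec keep their hydrogen count; the free hydrogens are
#' distributed over the free heavy atoms only.  Distinct partitions generate
#' disjoint isomer sets.
#'
#' @param concrete one concrete formula from [expandFormula()]
#' @return list of partitions; each is a data.frame with columns
#'   \code{symbol}, \code{nH}, \code{valence}, \code{effValence},
#'   \code{count}, sorted in the canonical type order
#' @export
distributeHydrogens <- function(concrete) {
  if (is.character(concrete)) {
    cf <- expandFormula(concrete)
    if (length(cf) != 1L)
      stop("formula does not expand to a single concrete formula")
    concrete <- cf[[1]]
  }
  freeC <- concrete$free[!names(concrete$free) %in% "H"]
  freeC <- freeC[freeC > 0]
  fx <- concrete$fixed
  freeH <- if ("H" %in% names(concrete$free)) concrete$free[["H"]] else 0L
  nHeavyFree <- sum(freeC)
  nFixed <- if (nrow(fx)) sum(fx$count) else 0L
  nAtoms <- nHeavyFree + nFixed

  finalize <- function(rows) {
    df <- do.call(rbind, rows)
    # merge identical united-atom types (a free atom that received k hydrogens
    # is indistinguishable from a {XHk} spec)
    key <- paste(df$symbol, df$nH)
    df <- data.frame(symbol = tapply(df$symbol, key, `[`, 1L)[unique(key)],
                     nH = tapply(df$nH, key, `[`, 1L)[unique(key)],
                     count = as.integer(tapply(df$count, key, sum)[unique(key)]),
                     stringsAsFactors = FALSE)
    df$valence <- .elementValence(df$symbol)
    df$effValence <- df$valence - df$nH
    if (nrow(df) == 0L) return(NULL)
    total <- sum(df$count)
    if (total > 1L && any(df$effValence < 1L)) return(NULL)
    if (total == 1L && any(df$effValence < 0L)) return(NULL)
    # completion requires an even valence sum and enough capacity
    if (sum(df$effValence * df$count) %% 2L != 0L) return(NULL)
    df <- .orderTypes(df)
    rownames(df) <- NULL
    df
  }

  if (nAtoms == 0L) {
    # hydrogen-only formulas: H2 is the single bonded pair
    if (freeH == 2L) {
      df <- finalize(list(data.frame(symbol = "H", nH = 0L, count = 2L,
                                     stringsAsFactors = FALSE)))
      return(if (is.null(df)) list() else list(df))
    }
    return(list())
  }

  # multisets of attached-H counts per free element
  singleAtom <- nAtoms == 1L
  perElement <- list()
  for (sym in names(freeC)) {
    m <- freeC[[sym]]
    val <- .elementValence(sym)
    maxH <- if (singleAtom) val else val - 1L
    combos <- list()
    rec <- function(left, cap, acc) {
      if (left == 0L) {
        combos[[length(combos) + 1L]] <<- acc
        return(invisible(NULL))
      }
      for (h in cap:0) rec(left - 1L, h, c(acc, h))
    }
    rec(m, maxH, integer(0))
    perElement[[sym]] <- combos
  }

  fixedRows <- if (nrow(fx)) {
    lapply(seq_len(nrow(fx)), function(k)
      data.frame(symbol = fx$symbol[k], nH = fx$nH[k], count = fx$count[k],
                 stringsAsFactors = FALSE))
  } else list()

  res <- list()
  syms <- names(freeC)
  assign1 <- function(k, hLeft, rows) {
    if (k > length(syms)) {
      if (hLeft != 0L) return(invisible(NULL))
      df <- finalize(c(rows, fixedRows))
      if (!is.null(df)) res[[length(res) + 1L]] <<- df
      return(invisible(NULL))
    }
    for (combo in perElement[[syms[k]]]) {
      used <- sum(combo)
      if (used > hLeft) next
      tb <- table(combo)
      rows2 <- c(rows, lapply(names(tb), function(h)
        data.frame(symbol = syms[k], nH = as.integer(h),
                   count = as.integer(tb[[h]]), stringsAsFactors = FALSE)))
      assign1(k + 1L, hLeft - used, rows2)
    }
  }
  assign1(1L, as.integer(freeH), list())
  res
}

# expand a partition into one row per united atom, with integer type ids
.partitionAtoms <- function(partition) {
  idx <- rep(seq_len(nrow(partition)), partition$count)
  at <- partition[idx, c("symbol", "nH", "valence", "effValence"), drop = FALSE]
  rownames(at) <- NULL
  at$type <- rep(seq_len(nrow(partition)), partition$count)
  at
}
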