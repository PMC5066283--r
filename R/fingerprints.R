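#' Construct a fingerprint
#'
#' A fixed-length bit vector with a dialect tag. Fingerprints from
#' different dialects (or lengths) are never comparable; [tanimoto()]
#' enforces this.
#'
#' @param bits Logical vector; length must be a positive multiple of 8.
#' @param dialect Dialect tag string recording how the bits were produced.
#' @return A `fingerprint` object.
#' @export
fingerprint <- function(bits, dialect) {
  bits <- as.logical(bits)
  if (anyNA(bits)) stop("bits must be TRUE/FALSE")
  if (length(bits) < 8L || length(bits) %% 8L != 0L)
    stop("fingerprint length must be a positive multiple of 8")
  structure(list(bits = bits, n_bits = length(bits),
                 dialect = as.character(dialect)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint>", x$n_bits, "bits,", sum(x$bits), "set, dialect:",
      x$dialect, "\n")
  invisible(x)
}

# 32-bit FNV-1a hash of a character string, exact in double arithmetic.
fnv1a_32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor_dbl(h, b %% 256)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# XOR of two nonnegative doubles < 2^32 (bitwXor works on 31-bit signed).
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(hi_a, hi_b) * 65536 + bitwXor(lo_a, lo_b)
}

# Enumerate the canonical strings of all simple linear atom/bond paths of
# 0..max_path bonds. Bond orders are encoded as -, =, #, ~; each path is
# read in both directions and the lexicographically smaller string kept.
linear_paths <- function(mol, max_path) {
  bond_char <- c("-", "=", "#", "~")
  nb <- lapply(seq_len(nrow(mol$atoms)), function(i) list())
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      o <- min(mol$bonds$order[k], 4L)
      nb[[a]][[length(nb[[a]]) + 1L]] <- c(b, o)
      nb[[b]][[length(nb[[b]]) + 1L]] <- c(a, o)
    }
  }
  elems <- mol$atoms$element
  acc <- new.env(parent = emptyenv())
  walk <- function(path_atoms, path_str) {
    rev_str <- reverse_path(path_str)
    canon <- if (path_str <= rev_str) path_str else rev_str
    assign(canon, TRUE, envir = acc)
    if (length(path_atoms) > max_path) return()
    tip <- path_atoms[length(path_atoms)]
    for (step in nb[[tip]]) {
      if (step[1] %in% path_atoms) next
      walk(c(path_atoms, step[1]),
           paste0(path_str, bond_char[step[2]], elems[step[1]]))
    }
  }
  for (i in seq_len(nrow(mol$atoms))) walk(i, elems[i])
  ls(acc)
}

# Reverse an element/bond path string, e.g. "C-N=O" -> "O=N-C".
reverse_path <- function(s) {
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?|[-=#~]", s))[[1]]
  paste(rev(toks), collapse = "")
}

#' Hashed linear-path 2D fingerprint
#'
#' Enumerates every simple linear path of up to `max_path` bonds in the
#' heavy-atom graph, writes it as an element/bond-order string (read in
#' its lexicographically canonical direction), and hashes each distinct
#' path into one of `n_bits` buckets with a 32-bit FNV-1a hash. The
#' dialect tag `vsb-linear/1;bits=<n>;maxpath=<k>` is recorded on every
#' fingerprint; absolute Tanimoto values are only comparable within one
#' dialect.
#'
#' @param mol A [molecule()].
#' @param n_bits Fingerprint length (>= 64, multiple of 8; default 1024).
#' @param max_path Maximum path length in bonds (default 7).
#' @return A [fingerprint()].
#' @export
linear_fingerprint <- function(mol, n_bits = 1024L, max_path = 7L) {
  stopifnot(inherits(mol, "molecule"))
  if (n_bits < 64L) stop("n_bits must be at least 64")
  if (n_bits %% 8L != 0L) stop("n_bits must be a multiple of 8")
  paths <- linear_paths(mol, max_path)
  bits <- logical(n_bits)
  for (p in paths) bits[fnv1a_32(p) %% n_bits + 1L] <- TRUE
  fingerprint(bits, sprintf("vsb-linear/1;bits=%d;maxpath=%d",
                            n_bits, max_path))
}

#' Tanimoto similarity of two fingerprints
#'
#' |intersection| / |union| of the set bits, in \[0, 1\]: 1 for identical
#' fingerprints ("same molecule"), 0 for disjoint bit sets ("no
#' similarity"). Two all-zero fingerprints compare as 1 (identical empty
#' molecules); the returned value then carries attribute
#' `both_empty = TRUE`.
#'
#' @param fp1,fp2 [fingerprint()] objects of identical length and dialect.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(fp1, fp2) {
  stopifnot(inherits(fp1, "fingerprint"), inherits(fp2, "fingerprint"))
  if (fp1$n_bits != fp2$n_bits)
    stop("fingerprint length mismatch: ", fp1$n_bits, " vs ", fp2$n_bits)
  if (fp1$dialect != fp2$dialect)
    stop("fingerprint dialect mismatch: '", fp1$dialect, "' vs '",
         fp2$dialect, "'")
  u <- sum(fp1$bits | fp2$bits)
  if (u == 0) return(structure(1, both_empty = TRUE))
  sum(fp1$bits & fp2$bits) / u
}

#' Mean pairwise similarity among a set of actives (Sim2D_act-act)
#'
#' Arithmetic mean of the Tanimoto similarity over all unordered distinct
#' pairs.
#'
#' @param fps List of at least two [fingerprint()] objects.
#' @return Mean similarity in \[0, 1\].
#' @export
mean_pairwise_similarity <- function(fps) {
  if (length(fps) < 2L) stop("need at least two fingerprints")
  pairs <- utils::combn(length(fps), 2)
  mean(apply(pairs, 2, function(ij)
    as.numeric(tanimoto(fps[[ij[1]]], fps[[ij[2]]]))))
}

#' Mean similarity of actives to a reference ligand (Sim2D_cryst-act)
#'
#' Mean Tanimoto of each active fingerprint against the reference
#' (typically the crystal-structure ligand used for docking).
#'
#' @param fps Non-empty list of [fingerprint()] objects.
#' @param ref Reference [fingerprint()] of the same dialect.
#' @return Mean similarity in \[0, 1\].
#' @export
mean_similarity_to_reference <- function(fps, ref) {
  if (!length(fps)) stop("need at least one fingerprint")
  mean(vapply(fps, function(f) as.numeric(tanimoto(f, ref)), 0))
}

#' Write fingerprints as a hex-string TSV
#'
#' First line records the dialect (`#dialect=<tag>`); then one
#' `id<TAB>hex` row per fingerprint.
#'
#' @param fps Named list of [fingerprint()] objects (one dialect).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  dialects <- unique(vapply(fps, `[[`, "", "dialect"))
  if (length(dialects) != 1) stop("mixed dialects in one file")
  hex <- vapply(fps, function(f)
    paste(sprintf("%02x", as.integer(packBits(f$bits, type = "raw"))),
          collapse = ""), "")
  writeLines(c(paste0("#dialect=", dialects),
               paste(names(fps) %||% seq_along(fps), hex, sep = "\t")),
             path)
  invisible(path)
}

#' Read fingerprints from a hex-string TSV
#'
#' @param path File written by [write_fingerprints()].
#' @return Named list of [fingerprint()] objects.
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#dialect=", lines[1])) stop("missing #dialect header line")
  dialect <- sub("^#dialect=", "", lines[1])
  rows <- strsplit(lines[-1], "\t")
  out <- lapply(rows, function(r) {
    bytes <- as.raw(strtoi(substring(r[2], seq(1, nchar(r[2]), 2),
                                     seq(2, nchar(r[2]), 2)), 16L))
    fingerprint(as.logical(rawToBits(bytes)), dialect)
  })
  names(out) <- vapply(rows, `[`, "", 1)
  out
}
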