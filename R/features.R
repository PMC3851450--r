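## Feature encodings. All encodings use the fixed alphabetical residue order
## AA_ALPHABET20 and return a named numeric vector with a "scheme" attribute.

FEATURE_SCHEMES <- c("AAC", "DIPEP", "PSEAAC", "NCC", "PHYSCHEM")

feature_vector <- function(values, names, scheme) {
  stopifnot(length(values) == length(names))
  v <- as.numeric(values)
  names(v) <- names
  attr(v, "scheme") <- scheme
  v
}

seq_chars <- function(record) {
  if (is.list(record) || is.data.frame(record)) s <- record$sequence else s <- record
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' Amino-acid composition (AAC)
#'
#' The 20-dimensional vector of relative occurrence frequencies of the
#' canonical amino acids, in alphabetical one-letter order. Entries sum to 1.
#'
#' @param record a single-row `protein_records` table, a list with a
#'   `sequence` field, or a plain canonical sequence string.
#' @return named numeric vector of length 20.
#' @examples
#' aac("ACDE")  # 0.25 at A, C, D, E
#' @export
aac <- function(record) {
  ch <- seq_chars(record)
  if (length(ch) < 1L) stop_data("AAC requires a sequence of length >= 1")
  counts <- table(factor(ch, levels = AA_ALPHABET20))
  feature_vector(as.numeric(counts) / length(ch), AA_ALPHABET20, "AAC")
}

#' Dipeptide composition (DIPEP)
#'
#' Relative frequencies of the 400 ordered adjacent residue pairs
#' (A.A, A.C, ..., Y.Y); a length-L sequence contributes L-1 dipeptides.
#' Entries sum to 1.
#'
#' @inheritParams aac
#' @return named numeric vector of length 400.
#' @export
dipep <- function(record) {
  ch <- seq_chars(record)
  L <- length(ch)
  if (L < 2L) stop_data("DIPEP requires a sequence of length >= 2")
  pairs <- paste0(ch[-L], ch[-1L])
  lv <- as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))
  counts <- table(factor(pairs, levels = lv))
  nm <- as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20,
                          function(a, b) paste0(a, ".", b))))
  feature_vector(as.numeric(counts) / (L - 1L), nm, "DIPEP")
}

## --- PseAAC ---------------------------------------------------------------

#' Physicochemical scales for pseudo amino-acid composition
#'
#' Tanford hydrophobicity and Hopp–Woods hydrophilicity, the pair of scales
#' classically used for the amphiphilic sequence-correlation factors. Both
#' are standardized to mean 0 / unit variance before use; alternatives can
#' be injected through [pseaac_params].
#' @name pseaac_scales
NULL

#' @rdname pseaac_scales
#' @export
TANFORD_HYDROPHOBICITY <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)

#' @rdname pseaac_scales
#' @export
HOPP_WOODS_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
  G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
  M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
  S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

#' Standardize a 20-residue physicochemical scale
#'
#' Centers to mean 0 and scales to unit variance over the 20 residues
#' (population denominator 20), the usual convention before computing
#' sequence-correlation factors.
#'
#' @param scale named numeric vector over the 20 canonical residues.
#' @return standardized named vector in alphabetical residue order.
#' @export
standardize_scale <- function(scale) {
  if (!all(AA_ALPHABET20 %in% names(scale)))
    stop_usage("scale must name all 20 canonical residues")
  v <- scale[AA_ALPHABET20]
  m <- mean(v)
  s <- sqrt(sum((v - m)^2) / 20)
  (v - m) / s
}

#' Parameters for pseudo amino-acid composition
#'
#' @param lam number of correlation tiers (lambda), default 5; must satisfy
#'   lambda < sequence length.
#' @param w weight of the sequence-order terms, default 0.1.
#' @param hydrophobicity,hydrophilicity injectable 20-residue scales
#'   (standardized internally).
#' @return a `pseaac_params` list.
#' @export
pseaac_params <- function(lam = 5L, w = 0.1,
                          hydrophobicity = TANFORD_HYDROPHOBICITY,
                          hydrophilicity = HOPP_WOODS_HYDROPHILICITY) {
  if (lam < 1L) stop_usage("lambda must be >= 1")
  if (w <= 0) stop_usage("w must be > 0")
  structure(list(lam = as.integer(lam), w = w,
                 h1 = standardize_scale(hydrophobicity),
                 h2 = standardize_scale(hydrophilicity)),
            class = "pseaac_params")
}

#' Pseudo amino-acid composition (PseAAC)
#'
#' Augments the amino-acid composition with 2*lambda amphiphilic
#' sequence-correlation factors. For each tier tau = 1..lambda two factors
#' are computed — theta1_tau from the standardized hydrophobicity scale and
#' theta2_tau from the standardized hydrophilicity scale — each as
#' `mean over i of H(P_i) * H(P_{i+tau})`. The full vector is
#' `f_u / D` for the first 20 entries and `w * theta / D` for the tail,
#' where `D = sum(f) + w * sum(theta)`; the tail is interleaved
#' theta1_1, theta2_1, theta1_2, theta2_2, ...
#'
#' @inheritParams aac
#' @param params a [pseaac_params] object.
#' @return named numeric vector of length `20 + 2*lam`.
#' @export
pseaac <- function(record, params = pseaac_params()) {
  ch <- seq_chars(record)
  L <- length(ch)
  lam <- params$lam
  if (L <= lam)
    stop_data(sprintf(
      "PseAAC requires sequence length L > lambda (L=%d, lambda=%d)", L, lam))
  f <- as.numeric(table(factor(ch, levels = AA_ALPHABET20))) / L
  h1 <- params$h1[ch]
  h2 <- params$h2[ch]
  theta <- numeric(2L * lam)
  for (tau in seq_len(lam)) {
    i <- seq_len(L - tau)
    theta[2L * tau - 1L] <- sum(h1[i] * h1[i + tau]) / (L - tau)
    theta[2L * tau]      <- sum(h2[i] * h2[i + tau]) / (L - tau)
  }
  D <- sum(f) + params$w * sum(theta)
  vals <- c(f / D, params$w * theta / D)
  nm <- c(AA_ALPHABET20,
          as.vector(rbind(paste0("theta1.", seq_len(lam)),
                          paste0("theta2.", seq_len(lam)))))
  feature_vector(vals, nm, "PSEAAC")
}

## --- NCC ------------------------------------------------------------------

#' Terminal N/Center/C segment composition (NCC)
#'
#' Concatenates the amino-acid compositions of the N-terminal segment, the
#' central region, and the C-terminal segment (60 features). When the
#' sequence is long enough (`L >= 2*terminal_len + 1`) the terminal segments
#' have exactly `terminal_len` residues (default 25); shorter sequences are
#' split into three contiguous near-equal thirds so that short proteins are
#' still representable. Each 20-block sums to 1.
#'
#' @inheritParams aac
#' @param terminal_len terminal segment length, default 25.
#' @return named numeric vector of length 60.
#' @export
ncc <- function(record, terminal_len = 25L) {
  ch <- seq_chars(record)
  L <- length(ch)
  if (L < 3L) stop_data("NCC requires a sequence of length >= 3")
  if (terminal_len < 1L) stop_usage("terminal_len must be >= 1")
  if (L >= 2L * terminal_len + 1L) {
    n1 <- terminal_len; n3 <- terminal_len
  } else {
    n1 <- ceiling(L / 3)
    rem <- L - n1
    n3 <- floor(rem / 2)
  }
  n2 <- L - n1 - n3
  segs <- list(N = ch[seq_len(n1)],
               Center = ch[seq.int(n1 + 1L, n1 + n2)],
               C = ch[seq.int(L - n3 + 1L, L)])
  blocks <- lapply(segs, function(s) {
    as.numeric(table(factor(s, levels = AA_ALPHABET20))) / length(s)
  })
  nm <- c(paste0("N.", AA_ALPHABET20), paste0("Center.", AA_ALPHABET20),
          paste0("C.", AA_ALPHABET20))
  feature_vector(unlist(blocks, use.names = FALSE), nm, "NCC")
}

## --- physicochemical classes and theoretical pI ---------------------------

#' Physicochemical property classes of the amino acids
#'
#' The 19 residue-membership classes used by [physchem] (overlapping classes
#' are allowed), plus a 20th computed feature, the theoretical isoelectric
#' point. Returned as a named list of residue sets; the `Theoretical.pI`
#' entry is `NA`, marking it as computed rather than membership-based.
#'
#' @return named list of length 20.
#' @export
property_class_table <- function() {
  list(
    Charged                  = c("D", "R", "E", "K", "H"),
    Hydrophilic.neutral      = c("N", "Q", "S", "T", "Y"),
    Basic.positive           = c("H", "K", "R"),
    Acidic.negative          = c("D", "E"),
    Aliphatic                = c("A", "G", "I", "L", "V"),
    Aromatic                 = c("F", "W", "Y"),
    Small                    = c("T", "D", "N"),
    Tiny                     = c("G", "A", "S", "P"),
    Large                    = c("F", "R", "W", "Y"),
    Hydrophobic.aromatic     = c("W", "F"),
    Hydrophobic.neutral      = c("A", "C", "G", "I", "L", "M", "F", "P", "W", "V"),
    Amidic                   = c("N", "Q"),
    Cyclic                   = "P",
    Hydroxylic               = c("S", "T"),
    Sulfur.containing        = c("C", "M"),
    H.bonding                = c("C", "W", "N", "Q", "S", "T", "Y", "K", "R",
                                 "H", "D", "E"),
    Acidic.and.amide         = c("D", "E", "N", "Q"),
    Ionizable                = c("D", "E", "H", "C", "Y", "K", "R"),
    Covalent.crosslink       = "C",
    Theoretical.pI           = NA
  )
}

## EMBOSS pKa values for the ionizable groups.
EMBOSS_PKA <- list(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, Y = 10.1,   # acidic side chains (lose H+)
  H = 6.5, K = 10.8, R = 12.5)           # basic side chains

#' Theoretical isoelectric point
#'
#' The pH at which the protein's net charge is zero, from
#' Henderson–Hasselbalch charge contributions of the free N- and C-terminus
#' and the ionizable side chains (D, E, C, Y, H, K, R) using the EMBOSS pKa
#' set, solved by bisection on pH 0–14 to 0.001 pH units.
#'
#' @inheritParams aac
#' @return pI in (0, 14).
#' @export
theoretical_pi <- function(record) {
  ch <- seq_chars(record)
  if (length(ch) < 1L) stop_data("pI requires a sequence of length >= 1")
  counts <- table(factor(ch, levels = AA_ALPHABET20))
  net_charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - EMBOSS_PKA$Nterm)) +
      sum(vapply(c("H", "K", "R"), function(r)
        counts[[r]] / (1 + 10^(ph - EMBOSS_PKA[[r]])), numeric(1)))
    neg <- 1 / (1 + 10^(EMBOSS_PKA$Cterm - ph)) +
      sum(vapply(c("C", "D", "E", "Y"), function(r)
        counts[[r]] / (1 + 10^(EMBOSS_PKA[[r]] - ph)), numeric(1)))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical property-class composition (PHYSCHEM)
#'
#' Features 1–19 are the fractions of residues belonging to each
#' physicochemical class of [property_class_table] (classes overlap, so the
#' features do not sum to 1); feature 20 is the theoretical isoelectric
#' point divided by 14, so that it is commensurate with the composition
#' fractions on \[0, 1\].
#'
#' @inheritParams aac
#' @param table a class table as from [property_class_table].
#' @return named numeric vector of length 20.
#' @export
physchem <- function(record, table = property_class_table()) {
  a <- aac(record)  # validates length >= 1
  nm <- names(table)
  vals <- numeric(length(table))
  for (k in seq_along(table)) {
    if (identical(nm[k], "Theoretical.pI")) {
      vals[k] <- theoretical_pi(record) / 14
    } else {
      vals[k] <- sum(a[table[[k]]])
    }
  }
  feature_vector(vals, nm, "PHYSCHEM")
}

## --- matrix extraction and composition comparison -------------------------

scheme_fun <- function(scheme, params = list()) {
  switch(scheme,
         AAC = function(s) aac(s),
         DIPEP = function(s) dipep(s),
         PSEAAC = {
           p <- if (!is.null(params$pseaac)) params$pseaac else
             pseaac_params(lam = if (!is.null(params$lam)) params$lam else 5L,
                           w = if (!is.null(params$w)) params$w else 0.1)
           function(s) pseaac(s, p)
         },
         NCC = {
           tl <- if (!is.null(params$terminal_len)) params$terminal_len else 25L
           function(s) ncc(s, tl)
         },
         PHYSCHEM = function(s) physchem(s),
         stop_usage(sprintf("unknown feature scheme '%s' (use one of %s)",
                            scheme, paste(FEATURE_SCHEMES, collapse = ", "))))
}

scheme_names <- function(scheme, params = list()) {
  probe <- paste(rep(AA_ALPHABET20, 6), collapse = "")
  names(scheme_fun(scheme, params)(probe))
}

#' Extract a feature matrix from a set of records
#'
#' Applies one encoding to every record. Row order follows input order;
#' records that fail the scheme's length precondition are excluded and
#' reported in the `excluded` attribute (id and reason) rather than silently
#' zeroed.
#'
#' @param records a `protein_records` table.
#' @param scheme one of `"AAC"`, `"DIPEP"`, `"PSEAAC"`, `"NCC"`, `"PHYSCHEM"`.
#' @param params optional list of scheme parameters (`pseaac` =
#'   [pseaac_params] object or `lam`/`w`; `terminal_len` for NCC).
#' @return numeric matrix (rows = records kept, named by id) with an
#'   `excluded` attribute (data frame id/reason) and a `scheme` attribute.
#' @export
extract <- function(records, scheme, params = list()) {
  fun <- scheme_fun(scheme, params)
  cols <- scheme_names(scheme, params)
  vals <- vector("list", nrow(records))
  reasons <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    res <- tryCatch(fun(records$sequence[i]), error = function(e) {
      reasons[i] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) vals[[i]] <- res   # [[<- NULL would shrink the list
  }
  keep <- !vapply(vals, is.null, logical(1))
  m <- matrix(numeric(0), nrow = 0, ncol = length(cols),
              dimnames = list(NULL, cols))
  if (any(keep))
    m <- do.call(rbind, vals[keep])
  rownames(m) <- records$id[keep]
  colnames(m) <- cols
  attr(m, "excluded") <- data.frame(id = records$id[!keep],
                                    reason = reasons[!keep],
                                    stringsAsFactors = FALSE)
  attr(m, "scheme") <- scheme
  m
}

#' Compare per-residue compositions of two sequence sets
#'
#' For each of the 20 residues, the mean amino-acid composition in each set,
#' their difference, and a two-tailed Welch t-test of the difference. Used to
#' screen for residues whose usage differs between classes (e.g. plastid vs
#' non-plastid proteins).
#'
#' @param set_a,set_b `protein_records` tables with at least 2 records each.
#' @return data frame with 20 rows: `residue`, `mean_a`, `mean_b`, `diff`,
#'   `t`, `p`.
#' @export
compare_compositions <- function(set_a, set_b) {
  if (nrow(set_a) < 2L || nrow(set_b) < 2L)
    stop_data("compare_compositions needs >= 2 records per set")
  ma <- extract(set_a, "AAC")
  mb <- extract(set_b, "AAC")
  res <- lapply(seq_along(AA_ALPHABET20), function(k) {
    xa <- ma[, k]; xb <- mb[, k]
    tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
    if (is.null(tt)) {  # degenerate: zero variance in both sets
      tval <- if (mean(xa) == mean(xb)) 0 else Inf * sign(mean(xa) - mean(xb))
      pval <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(residue = AA_ALPHABET20[k],
               mean_a = mean(xa), mean_b = mean(xb),
               diff = mean(xa) - mean(xb), t = tval, p = pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write / read a feature matrix as TSV
#'
#' First column is the record id; remaining columns are the scheme features.
#' The scheme name is echoed in a `# scheme=` comment line.
#'
#' @param m matrix from [extract].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_features <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme=%s", attr(m, "scheme") %||% "UNKNOWN"), con)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read '%s'", path))
  hdr <- readLines(path, n = 1L)
  scheme <- if (startsWith(hdr, "# scheme=")) sub("^# scheme=", "", hdr) else NA
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  attr(m, "scheme") <- scheme
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
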