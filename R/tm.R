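# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), per 5'->3' dinucleotide step.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

# duplex initiation terms per terminal base pair
NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

nn_dh_ds <- function(oligo) {
  ch <- strsplit(oligo, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  steps <- paste0(ch[-n], ch[-1L])
  dh <- sum(NN_DH[steps]) + NN_INIT_DH[[ch[1L]]] + NN_INIT_DH[[ch[n]]]
  ds <- sum(NN_DS[steps]) + NN_INIT_DS[[ch[1L]]] + NN_INIT_DS[[ch[n]]]
  c(dh = dh, ds = ds)
}

#' Oligo melting temperature
#'
#' Nearest-neighbor Tm under the SantaLucia (1998) unified parameter set:
#' duplex initiation terms per terminal base pair, a symmetry correction
#' for self-complementary oligos, and the entropic salt correction
#' `dS + 0.368 * (n-1) * ln[Na+]`. Default conditions are 50 mM monovalent
#' salt and 0.25 uM total strand concentration. A Wallace-rule fallback
#' (`2(A+T) + 4(G+C)`) is available for quick sanity arithmetic.
#'
#' @param oligo Oligo string over `{A,C,G,T}`, length >= 8 for the
#'   nearest-neighbor method.
#' @param method `"santalucia"` (default) or `"wallace"`.
#' @param Na Monovalent cation concentration in mol/L.
#' @param conc Total oligo strand concentration in mol/L.
#' @return Tm in degrees Celsius, rounded to 0.01.
#' @export
#' @examples
#' melting_temperature("ATGCATGCATGCATGCATGC")
melting_temperature <- function(oligo, method = c("santalucia", "wallace"),
                                Na = 0.05, conc = 0.25e-6) {
  method <- match.arg(method)
  stopifnot(is.character(oligo), length(oligo) == 1L)
  oligo <- toupper(oligo)
  ch <- strsplit(oligo, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% DNA_BASES4)) {
    stop("ambiguous or non-ACGT base in oligo: ", oligo)
  }
  if (method == "wallace") {
    return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
  }
  n <- length(ch)
  if (n < 8L) stop("nearest-neighbor Tm needs length >= 8, got ", n)

  hs <- nn_dh_ds(oligo)
  dh <- hs[["dh"]]
  ds <- hs[["ds"]]
  selfcomp <- oligo == revcomp(oligo)
  x <- 4
  if (selfcomp) {
    ds <- ds - 1.4
    x <- 1
  }
  ds <- ds + 0.368 * (n - 1L) * log(Na)
  tm <- 1000 * dh / (ds + 1.987 * log(conc / x)) - 273.15
  round(tm, 2)
}
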