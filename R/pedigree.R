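#' Build a multi-family nuclear pedigree with shared sires
#'
#' Families are nuclear (all full sibs share both parents); a sire may serve
#' several dams, as in the shared-sire breeding design of commercial salmon
#' populations. By default dams are assigned to sires round-robin, so with 10
#' sires and 20 dams each sire serves two dams.
#'
#' @param n_sires,n_dams founder counts.
#' @param offspring_per_family offspring per dam (>= 1).
#' @param seed integer seed (offspring sexes are random).
#' @param sire_of_dam optional integer vector of length `n_dams` giving the
#'   sire index of each dam; defaults to round-robin.
#' @return a data frame of class `pedigree` with columns id, sire, dam, sex
#'   ("M"/"F") and role ("founder"/"offspring"). Founders have `NA` parents.
#' @examples
#' ped <- make_pedigree(2, 4, 6, seed = 1)
#' table(ped$role)
#' @export
make_pedigree <- function(n_sires = 10, n_dams = 20, offspring_per_family = 8,
                          seed = 1, sire_of_dam = NULL) {
  stopifnot(n_sires >= 1, n_dams >= 1, offspring_per_family >= 1)
  sire_of_dam <- sire_of_dam %||% (((seq_len(n_dams) - 1L) %% n_sires) + 1L)
  stopifnot(length(sire_of_dam) == n_dams, all(sire_of_dam %in% seq_len(n_sires)))
  sires <- sprintf("S%03d", seq_len(n_sires))
  dams <- sprintf("D%03d", seq_len(n_dams))
  with_seed(seed, {
    off <- do.call(rbind, lapply(seq_len(n_dams), function(d) {
      data.frame(
        id = sprintf("O%03d_%02d", d, seq_len(offspring_per_family)),
        sire = sires[sire_of_dam[d]], dam = dams[d],
        sex = sample(c("M", "F"), offspring_per_family, replace = TRUE),
        role = "offspring", stringsAsFactors = FALSE)
    }))
    ped <- rbind(
      data.frame(id = sires, sire = NA_character_, dam = NA_character_,
                 sex = "M", role = "founder", stringsAsFactors = FALSE),
      data.frame(id = dams, sire = NA_character_, dam = NA_character_,
                 sex = "F", role = "founder", stringsAsFactors = FALSE),
      off)
    class(ped) <- c("pedigree", "data.frame")
    ped
  })
}

validate_pedigree <- function(ped) {
  off <- ped[ped$role == "offspring", ]
  miss <- setdiff(unique(c(off$sire, off$dam)), ped$id)
  if (length(miss) > 0)
    stopf("pedigree references missing parent(s): %s",
          paste(miss, collapse = ", "))
  invisible(ped)
}

#' Read/write a pedigree as a 4-column TSV (id, sire, dam, sex)
#'
#' Founders are rows whose sire and dam are both `0` (or empty).
#'
#' @param ped a `pedigree` data frame.
#' @param path file path.
#' @return `write_pedigree` returns the path invisibly; `read_pedigree`
#'   returns a `pedigree` data frame.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = ped$sex)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "character", "character"))
  d$sire[d$sire %in% c("0", "")] <- NA_character_
  d$dam[d$dam %in% c("0", "")] <- NA_character_
  d$role <- ifelse(is.na(d$sire) & is.na(d$dam), "founder", "offspring")
  class(d) <- c("pedigree", "data.frame")
  validate_pedigree(d)
  d
}
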