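#' Controlled vocabularies
#'
#' Syndrome and organism tokens accepted by the readers. The syndrome
#' vocabulary covers the RASopathy spectrum: neurofibromatosis type 1 (NF1),
#' Legius syndrome (LS), Noonan syndrome (NS), neurofibromatosis-Noonan
#' syndrome (NFNS), Noonan syndrome-like (NSL), Noonan syndrome with
#' multiple lentigines (NSML), Noonan syndrome-like with loose anagen hair
#' (NSLSH), Costello syndrome (CS), cardiofaciocutaneous syndrome (CFC),
#' capillary malformation-arteriovenous malformation (CM-AVM), juvenile
#' myelomonocytic leukemia (JMML), SYNGAP1-related intellectual
#' disability/autism ("Autism"), FGFR3-related skeletal disorders
#' ("FGFR3-related"), and "panel" for genes carried on diagnostic panels
#' without a syndrome assignment of their own.
#'
#' @return Character vector of accepted tokens.
#' @export
rasopathy_syndromes <- function() {
  c("NF1", "LS", "NS", "NFNS", "NSL", "NSML", "NSLSH", "CS", "CFC",
    "CM-AVM", "JMML", "Autism", "FGFR3-related", "panel")
}

#' @rdname rasopathy_syndromes
#' @export
known_organisms <- function() {
  c("human", "mouse", "rat", "monkey", "zebrafish")
}

# internal: normalize free-text organism labels to the controlled tokens
normalize_organism <- function(x) {
  key <- tolower(trimws(x))
  map <- c(
    human = "human", "homo sapiens" = "human", hsa = "human",
    mouse = "mouse", "mus musculus" = "mouse", mmu = "mouse",
    rat = "rat", "rattus norvegicus" = "rat", rno = "rat",
    monkey = "monkey", "macaca mulatta" = "monkey",
    zebrafish = "zebrafish", "danio rerio" = "zebrafish", dre = "zebrafish"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown organism token(s): ", paste(bad, collapse = ", "),
         " (accepted: ", paste(known_organisms(), collapse = ", "), ")",
         call. = FALSE)
  }
  out
}

#' Phosphosite notation
#'
#' A phosphosite is written as the one-letter acceptor residue (S, T or Y)
#' immediately followed by its 1-based position on the given sequence, e.g.
#' `"Y241"`. `parse_site()` and `render_site()` are exact inverses.
#'
#' @param x Site string such as `"Y241"`.
#' @param residue One-letter residue code.
#' @param position Integer position (>= 1).
#' @return `parse_site()`: a list with `residue` and `position`;
#'   `render_site()`: the site string.
#' @examples
#' parse_site("Y241")
#' render_site("S", 473)
#' @export
parse_site <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^([STY])([0-9]+)$", x))[[1]]
  if (length(m) != 3L) {
    stop("invalid site notation: '", x,
         "' (expected acceptor residue S/T/Y followed by a 1-based position)",
         call. = FALSE)
  }
  pos <- as.integer(m[3])
  if (pos < 1L) stop("site position must be >= 1", call. = FALSE)
  list(residue = m[2], position = pos)
}

#' @rdname parse_site
#' @export
render_site <- function(residue, position) {
  stopifnot(residue %in% c("S", "T", "Y"), position >= 1)
  paste0(residue, as.integer(position))
}
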