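#' Nuclease specification for cut-site prediction
#'
#' Coordinates are 0-based half-open intervals on the reference strand;
#' predicted cut sites are inter-base indices (`k` means between bases
#' `k - 1` and `k`).
#'
#' For CRISPR, each guide is a protospacer interval plus strand; the PAM
#' lies immediately 3' of the protospacer (to the right of a plus-strand
#' guide, to the left of a minus-strand guide, in reference coordinates).
#' Dual-guide systems (paired nickases) carry two guides. TALEN and
#' FokI-dCas9 pairs are described by their left/right DNA-binding
#' intervals, which must not overlap.
#'
#' @param protospacer Integer interval `c(start, end)`.
#' @param strand `"+"` or `"-"`.
#' @param kind One of `"crispr"`, `"talen"`, `"fokI_dcas9"`.
#' @param guides List of [crispr_guide()] objects (1 for single systems,
#'   exactly 2 for dual nickase systems).
#' @param arms For TALEN/FokI-dCas9: list of the two binding intervals
#'   (left, right).
#' @return `crispr_guide()` returns a `crispr_guide`; `nuclease_spec()`
#'   returns a `nuclease_spec`.
#' @export
crispr_guide <- function(protospacer, strand = c("+", "-")) {
  strand <- match.arg(strand)
  structure(list(protospacer = iv_check(protospacer, "protospacer"),
                 strand = strand),
            class = "crispr_guide")
}

#' @rdname crispr_guide
#' @export
nuclease_spec <- function(kind = c("crispr", "talen", "fokI_dcas9"),
                          guides = list(), arms = list()) {
  kind <- match.arg(kind)
  if (kind == "crispr") {
    if (length(guides) < 1L || length(guides) > 2L ||
        !all(vapply(guides, inherits, logical(1), "crispr_guide")))
      stop("crispr spec needs 1 (single) or 2 (dual) crispr_guide objects")
  } else {
    if (length(arms) != 2L)
      stop(kind, " spec needs exactly two binding intervals (left, right)")
    arms <- lapply(seq_along(arms), function(i)
      iv_check(arms[[i]], paste0("arm ", i)))
    if (arms[[1]][1] > arms[[2]][1]) arms <- arms[c(2, 1)]
    if (arms[[1]][2] > arms[[2]][1])
      stop("binding intervals overlap; no spacer to cut in")
  }
  structure(list(kind = kind, guides = guides, arms = arms),
            class = "nuclease_spec")
}

#' Predict nuclease cut sites
#'
#' CRISPR guides cut 3 bp upstream of the PAM: a plus-strand protospacer
#' `[s, e)` (PAM at `[e, e+3)`) cuts at inter-base position `e - 3`; the
#' mirror-symmetric convention puts a minus-strand cut at `s + 3`. TALEN
#' and FokI-dCas9 pairs cut equidistant between their DNA-binding
#' intervals (midpoint of the spacer, floored for odd spacer lengths).
#' Dual-guide systems return one site per guide.
#'
#' @param spec A [nuclease_spec()].
#' @return Integer vector of inter-base cut positions.
#' @examples
#' g <- crispr_guide(c(100, 120), "+")
#' predict_cut_sites(nuclease_spec("crispr", guides = list(g)))  # 117
#' @export
predict_cut_sites <- function(spec) {
  stopifnot(inherits(spec, "nuclease_spec"))
  if (spec$kind == "crispr") {
    vapply(spec$guides, function(g) {
      if (g$strand == "+") g$protospacer[2] - 3L else g$protospacer[1] + 3L
    }, integer(1))
  } else {
    as.integer((spec$arms[[1]][2] + spec$arms[[2]][1]) %/% 2L)
  }
}

#' Assay layout: amplicon, primers, probes, cut sites, donor, edit
#'
#' Interval model of a ddPCR editing assay, all coordinates 0-based
#' half-open on the reference strand. Primer intervals must sit at the two
#' ends of the amplicon; all features must lie within it.
#'
#' @param amplicon,fwd_primer,rev_primer,ref_probe Integer intervals.
#' @param hdr_probe Optional HDR (gain) probe interval.
#' @param nhej_probes List of NHEJ (drop-off) probe intervals.
#' @param dark_probe Optional dark-probe interval.
#' @param cut_sites Integer vector of predicted inter-base cut positions
#'   (or a [nuclease_spec()], whose sites are predicted).
#' @param donor_span Optional interval covered by the donor molecule.
#' @param edit_pos Optional 0-based position of the intended edit.
#' @return An object of class `assay_layout`.
#' @seealso [validate_layout()], [predict_cut_sites()]
#' @export
assay_layout <- function(amplicon, fwd_primer, rev_primer, ref_probe,
                         hdr_probe = NULL, nhej_probes = list(),
                         dark_probe = NULL, cut_sites = integer(),
                         donor_span = NULL, edit_pos = NULL) {
  amplicon <- iv_check(amplicon, "amplicon")
  fwd_primer <- iv_check(fwd_primer, "fwd_primer")
  rev_primer <- iv_check(rev_primer, "rev_primer")
  ref_probe <- iv_check(ref_probe, "ref_probe")
  hdr_probe <- iv_check(hdr_probe, "hdr_probe", allow_null = TRUE)
  dark_probe <- iv_check(dark_probe, "dark_probe", allow_null = TRUE)
  donor_span <- iv_check(donor_span, "donor_span", allow_null = TRUE)
  nhej_probes <- lapply(seq_along(nhej_probes), function(i)
    iv_check(nhej_probes[[i]], paste0("nhej_probes[[", i, "]]")))
  if (inherits(cut_sites, "nuclease_spec"))
    cut_sites <- predict_cut_sites(cut_sites)
  if (length(cut_sites) &&
      (any(!is.finite(cut_sites)) || any(cut_sites != floor(cut_sites))))
    stop("cut_sites must be integer positions")
  cut_sites <- as.integer(cut_sites)
  if (!is.null(edit_pos)) edit_pos <- assert_count(edit_pos, "edit_pos")

  if (fwd_primer[1] != amplicon[1] || rev_primer[2] != amplicon[2])
    stop("primer intervals must sit at the amplicon ends")
  for (nm in c("fwd_primer", "rev_primer", "ref_probe")) {
    if (!iv_within(get(nm), amplicon))
      stop(nm, " must lie within the amplicon")
  }
  inner <- c(hdr_probe = list(hdr_probe), dark_probe = list(dark_probe))
  for (nm in names(inner))
    if (!is.null(inner[[nm]]) && !iv_within(inner[[nm]], amplicon))
      stop(nm, " must lie within the amplicon")
  for (p in nhej_probes)
    if (!iv_within(p, amplicon)) stop("NHEJ probe outside the amplicon")
  if (length(cut_sites) &&
      (any(cut_sites < amplicon[1]) || any(cut_sites > amplicon[2])))
    stop("cut sites must lie within the amplicon")
  if (!is.null(edit_pos) && (edit_pos < amplicon[1] ||
                             edit_pos >= amplicon[2]))
    stop("edit_pos must lie within the amplicon")

  structure(list(amplicon = amplicon, fwd_primer = fwd_primer,
                 rev_primer = rev_primer, ref_probe = ref_probe,
                 hdr_probe = hdr_probe, nhej_probes = nhej_probes,
                 dark_probe = dark_probe, cut_sites = cut_sites,
                 donor_span = donor_span, edit_pos = edit_pos),
            class = "assay_layout")
}

#' Validate an assay layout against the design rules
#'
#' Checks, with one pass/fail row per rule:
#' \describe{
#'   \item{cut_site_flanks}{every cut site sits mid-amplicon with 75-125 bp
#'     between it and each inner primer boundary;}
#'   \item{primer_outside_donor}{at least one primer interval is disjoint
#'     from the donor span, so only integrated edits are quantified;}
#'   \item{ref_probe_distant}{the reference probe is disjoint from an
#'     exclusion window around every cut site (default 30 bp each side)
#'     and from the donor span;}
#'   \item{nhej_probe_on_cut}{every NHEJ probe strictly spans a cut site
#'     (so an indel there destroys its binding site);}
#'   \item{hdr_probe_on_edit}{the HDR probe interval contains the edit
#'     position.}
#' }
#' Rules whose features are absent from the layout pass vacuously with an
#' explanatory message.
#'
#' @param layout An [assay_layout()].
#' @param flank_min,flank_max Allowed cut-to-primer flank range in bp
#'   (defaults 75 and 125).
#' @param cut_exclusion Half-width in bp of the reference-probe exclusion
#'   window around each cut site (default 30).
#' @return A data frame of class `layout_report` with columns `rule`,
#'   `pass`, `message`; attribute `all_pass`.
#' @export
validate_layout <- function(layout, flank_min = 75, flank_max = 125,
                            cut_exclusion = 30) {
  stopifnot(inherits(layout, "assay_layout"))
  rules <- list()
  add <- function(rule, pass, message)
    rules[[length(rules) + 1L]] <<- data.frame(rule = rule, pass = pass,
                                               message = message)

  inner_left <- layout$fwd_primer[2]
  inner_right <- layout$rev_primer[1]
  if (length(layout$cut_sites) == 0L) {
    add("cut_site_flanks", TRUE, "no cut sites declared")
  } else {
    fl <- layout$cut_sites - inner_left
    fr <- inner_right - layout$cut_sites
    ok <- all(fl >= flank_min & fl <= flank_max &
                fr >= flank_min & fr <= flank_max)
    add("cut_site_flanks", ok,
        sprintf("flanks to inner primer boundaries: %s",
                paste(sprintf("%d/%d", fl, fr), collapse = ", ")))
  }

  if (is.null(layout$donor_span)) {
    add("primer_outside_donor", TRUE, "no donor span declared")
  } else {
    fwd_out <- iv_disjoint(layout$fwd_primer, layout$donor_span)
    rev_out <- iv_disjoint(layout$rev_primer, layout$donor_span)
    add("primer_outside_donor", fwd_out || rev_out,
        sprintf("forward primer %s donor; reverse primer %s donor",
                if (fwd_out) "outside" else "inside",
                if (rev_out) "outside" else "inside"))
  }

  ref_ok <- TRUE; ref_msg <- character()
  for (k in layout$cut_sites) {
    win <- c(k - cut_exclusion, k + cut_exclusion)
    if (iv_overlaps(layout$ref_probe, win)) {
      ref_ok <- FALSE
      ref_msg <- c(ref_msg,
                   sprintf("overlaps %d bp exclusion window of cut %d",
                           cut_exclusion, k))
    }
  }
  if (!is.null(layout$donor_span) &&
      iv_overlaps(layout$ref_probe, layout$donor_span)) {
    ref_ok <- FALSE
    ref_msg <- c(ref_msg, "overlaps the donor span")
  }
  add("ref_probe_distant", ref_ok,
      if (ref_ok) "reference probe clear of cut sites and donor"
      else paste(ref_msg, collapse = "; "))

  if (length(layout$nhej_probes) == 0L) {
    add("nhej_probe_on_cut", TRUE, "no NHEJ probes declared")
  } else if (length(layout$cut_sites) == 0L) {
    add("nhej_probe_on_cut", FALSE,
        "NHEJ probes declared but no cut sites to span")
  } else {
    spans <- vapply(layout$nhej_probes, function(p)
      any(layout$cut_sites > p[1] & layout$cut_sites < p[2]), logical(1))
    add("nhej_probe_on_cut", all(spans),
        sprintf("%d of %d NHEJ probes span a cut site",
                sum(spans), length(spans)))
  }

  if (is.null(layout$hdr_probe) || is.null(layout$edit_pos)) {
    add("hdr_probe_on_edit", TRUE, "no HDR probe/edit position declared")
  } else {
    ok <- layout$edit_pos >= layout$hdr_probe[1] &&
      layout$edit_pos < layout$hdr_probe[2]
    add("hdr_probe_on_edit", ok,
        sprintf("edit position %d %s HDR probe [%d, %d)",
                layout$edit_pos, if (ok) "inside" else "outside",
                layout$hdr_probe[1], layout$hdr_probe[2]))
  }

  report <- do.call(rbind, rules)
  attr(report, "all_pass") <- all(report$pass)
  class(report) <- c("layout_report", "data.frame")
  report
}

#' @export
print.layout_report <- function(x, ...) {
  cat("Assay layout rule report:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-21s %s\n",
                if (x$pass[i]) "PASS" else "FAIL", x$rule[i], x$message[i]))
  invisible(x)
}

#' Read a reference sequence from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}
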