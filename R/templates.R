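# Template specifications for the primer-extension assay.
#
# The template strand is written 5'->3'; its 3'-terminal base is a
# non-extensible dideoxy-C that completes the primer-binding duplex, so the
# polymerase copies only the extension region (the bases 5' of the
# primer-binding site), walking the template 3'->5'.  The theoretical
# error-free extension product is therefore the reverse complement of the
# extension region, and "extension order" position p (1-based, the order in
# which product bases are added) corresponds to template base
# `rev(extension_region)[p]`.

LEFT_PRIMER_BIND <- "GATGGTCATAGCTGTTGTA"  # primer 3' tail, read layout landmark
RIGHT_ADAPTER_PREFIX <- "AGATCGGAAGAG"     # first 12 bases of the ligated adapter

TEMPLATE_ORIGINAL <- paste0(
  "AAAATCATAACTAAGTCAGTCAGTACGTCAGTAGCTCAGTCGATGGATGCAATGAATGAATGAATGAAAATAAAAA",
  "TACAACAGCTATGACCAT")  # + ddC terminator
TEMPLATE_SWAPPED <- paste0(
  "CGATGGATGCAATGAATGAATGAATGAAAATAAAAAAAAATCATAACTAAGTCAGTCAGTACGTCAGTAGCTCAGT",
  "TACAACAGCTATGACCAT")  # + ddC terminator

#' Template specification
#'
#' Build a template specification for a primer-extension assay.  The
#' extension region is the part of the template 5' of the primer-binding
#' site; the alignment reference (`product_ref`) is its reverse complement,
#' i.e. the theoretical error-free extension product read 5'->3'.
#'
#' @param name label for the template.
#' @param template_seq template strand 5'->3', excluding the terminal ddC.
#' @param primer_binding_len number of 3'-terminal template bases annealed to
#'   the primer (excluding the ddC, which pairs with the primer's final base).
#' @return an object of class `template_spec` with fields `name`,
#'   `template_seq`, `primer_binding_len`, `extension_region` (template
#'   5'->3'), `ext_len`, `product_ref`, and `template_ext_order` (per-position
#'   template bases in the order the polymerase copies them).
#' @examples
#' tpl <- template_spec("toy", "AACGTTACGT", 4)
#' tpl$product_ref
#' @export
template_spec <- function(name, template_seq, primer_binding_len) {
  stopifnot(is.character(template_seq), length(template_seq) == 1L,
            nchar(template_seq) > primer_binding_len, primer_binding_len >= 0)
  template_seq <- toupper(template_seq)
  if (grepl("[^ACGT]", template_seq)) {
    stop("template_seq must contain only A/C/G/T")
  }
  ext_len <- nchar(template_seq) - primer_binding_len
  ext <- substr(template_seq, 1L, ext_len)
  ext_order <- rev(split_chars(ext)[[1L]])
  structure(list(
    name = name,
    template_seq = template_seq,
    primer_binding_len = primer_binding_len,
    extension_region = ext,
    ext_len = ext_len,
    product_ref = revcomp(ext),
    template_ext_order = ext_order
  ), class = "template_spec")
}

#' Bundled assay templates
#'
#' The two 94-nt template strands used throughout the package: the original
#' template and the half-swapped variant in which the first 36 and the
#' following 40 bases of the extension region are exchanged.  Both have a
#' 76-base extension region and an 18-base primer-binding tail (plus the
#' ddC terminator, which pairs with the primer's 3'-terminal base).
#'
#' @param name `"original"` or `"swapped"`.
#' @return a [template_spec()] object.
#' @export
bundled_template <- function(name = c("original", "swapped")) {
  name <- match.arg(name)
  seqs <- c(original = TEMPLATE_ORIGINAL, swapped = TEMPLATE_SWAPPED)
  template_spec(name, seqs[[name]], primer_binding_len = 18L)
}

#' @export
print.template_spec <- function(x, ...) {
  cat("Template", x$name, "-", nchar(x$template_seq), "nt,",
      x$ext_len, "nt extension region\n")
  cat("  product reference:", x$product_ref, "\n")
  invisible(x)
}
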