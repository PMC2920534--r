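#' Reference biopanning panels from the colorectal-cancer serum study
#'
#' The worked reference fixture: peptide inventories selected by biopanning
#' on serum IgG/IgM antibodies of four colorectal-cancer patients (A-D) and a
#' healthy-donor control, with clonal copy numbers. The published table's
#' typesetting concatenates some inserts within one cell, so this fixture
#' encodes one documented reading:
#'
#' * Patient B: `KSNKCFM` and `KQSGHHRSE` are read as two inserts; under this
#'   reading five phage particles carry the `KxxGHH` motif (matching the
#'   published motif count), while the panel total is 12 phage rather than
#'   the published 14 — the remainder is not reconstructable from the table.
#' * Patient D (IgG): long concatenated-looking cells are kept as single
#'   inserts; this reading yields exactly five distinct `PWSK`-containing
#'   peptides, the count behind the shared-motif (glycogen-phosphorylase)
#'   negation argument.
#' * Normal control: the first concatenated cell is split at 10-mer library
#'   boundaries, giving six entries; the split points are this package's
#'   choice.
#'
#' @param path Optional path; when given, the fixture is also written as a
#'   panel TSV there.
#' @return A panel tibble (see [read_panels()]). The patient A IgG panel is
#'   exactly `TGVRGQRISQ` (9 copies), `QNPGETSKMN` (6), `KYRWYK` (3): 18
#'   phage particles, the dominant insert in nine of them.
#' @export
table1_panels <- function(path = NULL) {
  df <- tibble::tribble(
    ~patient_id, ~antibody_class, ~sequence, ~copy_number,
    "A", "IgG", "TGVRGQRISQ", 9L,
    "A", "IgG", "QNPGETSKMN", 6L,
    "A", "IgG", "KYRWYK", 3L,
    "A", "IgM", "AVHFPDDLITPGD", 2L,
    "A", "IgM", "AEPPFEF", 2L,
    "A", "IgM", "PSKAAYVV", 3L,
    "A", "IgM", "QDLYSSA", 3L,
    "A", "IgM", "QDIFSSA", 3L,
    "A", "IgM", "MSSVMTY", 1L,
    "A", "IgM", "FQSPK", 2L,
    "A", "IgM", "ASHQNRPFRQAAS", 1L,
    "B", "IgG", "FSRRAQQVGAK", 3L,
    "B", "IgG", "DHNRSMSHNRVSNK", 1L,
    "B", "IgG", "KGMGHHGNG", 1L,
    "B", "IgG", "KAYGHHLSAE", 2L,
    "B", "IgG", "GLGVGHKSYSGYWHSWIFGA", 1L,
    "B", "IgG", "KSHGHHR", 1L,
    "B", "IgG", "KSNKCFM", 1L,
    "B", "IgG", "KQSGHHRSE", 1L,
    "B", "IgG", "WTRRPYDELIV", 1L,
    "C", "IgG", "KENGRSPTHS", 10L,
    "C", "IgG", "GRSNKSG", 1L,
    "C", "IgG", "SPTHP", 5L,
    "C", "IgG", "GRRNKSG", 1L,
    "D", "IgG", "VPWSKPWWTQGHNNHNRHHP", 1L,
    "D", "IgG", "SNVRSFDNPIANTPWSKTL", 2L,
    "D", "IgG", "IPLPPPSRPF", 2L,
    "D", "IgG", "HNTRNWTLPP", 1L,
    "D", "IgG", "SNVISYPDVGNPWSKQINIVNTTSYNMRP", 2L,
    "D", "IgG", "LPWSKLSSPSSNVKNYMAIPQLHPHNLHSP", 1L,
    "D", "IgG", "TLHTTHSPFK", 1L,
    "D", "IgG", "NYEPVPRGAR", 1L,
    "D", "IgG", "TDAAPWSKVT", 2L,
    "D", "IgG", "GKSLHGSHHP", 1L,
    "D", "IgG", "SNVISFRHAS", 1L,
    "D", "IgG", "TNVISYTPLY", 3L,
    "D", "IgM", "QSLDHSSC", 5L,
    "D", "IgM", "LNPQSPRD", 4L,
    "D", "IgM", "YSWRAT", 4L,
    "D", "IgM", "NERSEAR", 1L,
    "D", "IgM", "HFHHLAVRGRPQGWLGWGTVEPDPTRWGARLVK", 1L,
    "D", "IgM", "GGRWNR", 2L,
    "D", "IgM", "PETTDK", 2L,
    "D", "IgM", "PGHVRGTLGR", 2L,
    "D", "IgM", "YVDTLSKLRGQSLA", 1L,
    "D", "IgM", "AVRRPD", 4L,
    "D", "IgM", "QRLAAGFHQLAETLF", 1L,
    "D", "IgM", "GRKTELF", 1L,
    "D", "IgM", "YLASPFE", 1L,
    "D", "IgM", "FRVARAARTGRMWRLVYPQQVVGLVP", 2L,
    "D", "IgM", "QIQLSGG", 1L,
    "D", "IgM", "VKNRGR", 1L,
    "Normal control", "IgG", "DIRLSAQLSW", 1L,
    "Normal control", "IgG", "SGYYTYTNGV", 1L,
    "Normal control", "IgG", "HHGRGLYNFMGK", 1L,
    "Normal control", "IgG", "RRTDYLLNGDPTVSESS", 1L,
    "Normal control", "IgG", "APQGYLFKESSTKSE", 1L,
    "Normal control", "IgG", "NQHLILSVGSIAAAVHRANKEPAT", 1L
  )
  df$source_label <- "reference-table"
  out <- as_peptide_panels(df)
  if (!is.null(path)) write_panels(out, path)
  out
}
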