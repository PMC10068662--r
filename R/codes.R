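# Bundled catalogs: monitored signals, drugs, step events, care units and a
# small ICD-10-like / CCAM-like code list. The code list is illustrative (a
# real deployment would plug in the national terminologies); it includes a
# marked "extracorporeal circulation" subset so code-grouping features can be
# exercised without any terminology download.

#' Catalog of monitored intraoperative signals
#'
#' Baseline, noise and physiological bounds drive the synthetic generator;
#' `lo`/`hi` double as the default plausibility range for quality flagging.
#' `ar1` is the lag-1 autocorrelation of the simulated noise.
#'
#' @return a `data.table` with one row per signal
#'   (`signal_code`, `label`, `unit`, `baseline`, `sd`, `ar1`, `lo`, `hi`).
#' @export
#' @examples
#' signal_catalog()
signal_catalog <- function() {
  data.table(
    signal_code = c("MAP", "SBP", "DBP", "HR", "SPO2", "ETCO2", "TV"),
    label = c("mean arterial pressure", "systolic arterial pressure",
              "diastolic arterial pressure", "heart rate",
              "oxygen saturation", "end-tidal co2", "tidal volume"),
    unit = c("mmHg", "mmHg", "mmHg", "bpm", "%", "mmHg", "mL"),
    baseline = c(85, 120, 65, 75, 98, 35, 450),
    sd = c(5, 8, 5, 6, 0.8, 2, 30),
    ar1 = c(0.85, 0.85, 0.85, 0.8, 0.7, 0.8, 0.6),
    lo = c(30, 50, 20, 20, 70, 10, 100),
    hi = c(150, 250, 140, 250, 100, 80, 1200)
  )
}

step_event_labels <- function() {
  c("anesthesia start", "surgery start", "surgery end", "anesthesia end")
}

drug_catalog <- function() {
  data.table(
    drug_label = c("propofol", "sufentanil", "cefazolin", "ephedrine",
                   "atracurium", "norepinephrine", "ketamine", "dexamethasone"),
    dose_lo = c(80, 0.01, 1000, 3, 20, 0.05, 10, 4),
    dose_hi = c(250, 0.05, 2000, 30, 60, 0.5, 50, 8),
    dose_unit = rep("mg", 8)
  )
}

care_units <- function() {
  c("cardiac surgery", "vascular surgery", "orthopedics",
    "digestive surgery", "neurosurgery", "urology")
}

biology_catalog <- function() {
  data.table(
    analyte = c("hemoglobin", "creatinine", "hstnt", "lactate"),
    unit = c("g/dL", "umol/L", "ng/L", "mmol/L"),
    lo = c(9, 45, 3, 0.4),
    hi = c(16, 130, 60, 2.5)
  )
}

#' Bundled ICD-10-like and CCAM-like code lists
#'
#' About fifty plausible codes. CCAM-like procedure codes carry an `ecc` flag
#' marking the subset performed under extracorporeal circulation, which feeds
#' the code-grouping feature.
#'
#' @return `icd10_codes()`: a `data.table` (`code`, `label`);
#'   `ccam_codes()`: a `data.table` (`code`, `label`, `ecc`).
#' @export
icd10_codes <- function() {
  data.table(
    code = c("I10", "I25.1", "I48.0", "I50.9", "I65.2", "I70.2", "I71.4",
             "E11.9", "E66.9", "E78.5", "J44.9", "J45.9", "N18.3", "N20.0",
             "K40.9", "K80.2", "C18.9", "C61", "M16.1", "M17.1", "Z95.1",
             "D64.9", "F17.2", "G47.3", "R07.4"),
    label = c("essential hypertension", "atherosclerotic heart disease",
              "paroxysmal atrial fibrillation", "heart failure",
              "carotid occlusion and stenosis",
              "atherosclerosis of arteries of extremities",
              "abdominal aortic aneurysm", "type 2 diabetes", "obesity",
              "hyperlipidaemia", "copd", "asthma",
              "chronic kidney disease stage 3", "calculus of kidney",
              "inguinal hernia", "calculus of gallbladder",
              "malignant neoplasm of colon", "malignant neoplasm of prostate",
              "coxarthrosis", "gonarthrosis", "aortocoronary bypass status",
              "anaemia", "nicotine dependence", "sleep apnoea", "chest pain")
  )
}

#' @rdname icd10_codes
#' @export
ccam_codes <- function() {
  dt <- data.table(
    code = c("DZEA002", "DZCA005", "DZKA003", "DDMA012", "DGFA009",
             "EBLA004", "DZNA001",
             "EDAF008", "EPLF002", "NEKA020", "NFKA007", "HHFA016",
             "JGFA015", "LMMA004", "GFFA001", "HMFC004", "EJGA001",
             "AFLB010", "QZFA001", "DEQP003", "GLLD012", "FCFA009",
             "HPLB002", "JVJF004", "ZZLP025"),
    label = c("aortic valve replacement with cardiopulmonary bypass",
              "mitral valve repair with cardiopulmonary bypass",
              "coronary artery bypass grafting with cardiopulmonary bypass",
              "ascending aorta replacement with cardiopulmonary bypass",
              "pulmonary thromboendarterectomy with cardiopulmonary bypass",
              "cardiac tumour resection with cardiopulmonary bypass",
              "heart transplantation with cardiopulmonary bypass",
              "endovascular aortic aneurysm repair",
              "carotid endarterectomy", "total hip replacement",
              "total knee replacement", "laparoscopic cholecystectomy",
              "radical prostatectomy", "lumbar discectomy",
              "pulmonary lobectomy", "colectomy", "varicose vein stripping",
              "ventriculoperitoneal shunt", "skin graft",
              "electrocardiogram", "mechanical ventilation",
              "lymph node dissection", "abdominal wall repair",
              "bladder catheterization", "anesthesia consultation"),
    ecc = c(rep(TRUE, 7), rep(FALSE, 18))
  )
  dt
}

#' Codes marking surgery under extracorporeal circulation
#' @return character vector of CCAM-like codes.
#' @export
ecc_code_set <- function() ccam_codes()[ecc == TRUE, code]
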