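{
  "version": "1.0",
  "frame_convention": {
    "x": "mediolateral, +x toward lateral (right-knee canonical side)",
    "y": "anteroposterior, +y toward anterior",
    "z": "proximodistal, +z toward proximal (scanner table axis)",
    "note": "refine_axis/refine_sense are interpreted in this reference frame"
  },
  "landmarks": [
    {"acronym": "FME",   "bone": "femur", "description": "Medial epicondyle: anterodistal osseous prominence on the medial aspect of the distal femur", "refine_axis": "x", "refine_sense": "min", "secondary_axis": "y", "secondary_sense": "max"},
    {"acronym": "FLE",   "bone": "femur", "description": "Lateral epicondyle: anterodistal osseous prominence on the lateral aspect of the distal femur", "refine_axis": "x", "refine_sense": "max", "secondary_axis": "y", "secondary_sense": "max"},
    {"acronym": "FMCP",  "bone": "femur", "description": "Most posterior point of the medial femoral condyle", "refine_axis": "y", "refine_sense": "min", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FLCP",  "bone": "femur", "description": "Most posterior point of the lateral femoral condyle", "refine_axis": "y", "refine_sense": "min", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FMCD",  "bone": "femur", "description": "Most distal point of the medial femoral condyle", "refine_axis": "z", "refine_sense": "min", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FLCD",  "bone": "femur", "description": "Most distal point of the lateral femoral condyle", "refine_axis": "z", "refine_sense": "min", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FMTA",  "bone": "femur", "description": "Most anterior point of the medial trochlea", "refine_axis": "y", "refine_sense": "max", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FLTA",  "bone": "femur", "description": "Most anterior point of the lateral trochlea", "refine_axis": "y", "refine_sense": "max", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FMCPP", "bone": "femur", "description": "Most proximal cartilage point at the posterior medial condyle (sagittal-view construction)", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FLCPP", "bone": "femur", "description": "Most proximal cartilage point at the posterior lateral condyle (sagittal-view construction)", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "Notch", "bone": "femur", "description": "Deepest (most anterior) midline point of the intercondylar notch on a caudocranial view; view-constrained construction", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FMCIP", "bone": "femur", "description": "Most lateral cartilage point of the medial condyle at one third of the notch depth (coronal-view construction)", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FMCEP", "bone": "femur", "description": "Most medial cartilage point of the medial condyle at one third of the notch depth (coronal-view construction)", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FLCIP", "bone": "femur", "description": "Most medial cartilage point of the lateral condyle at one third of the notch depth (coronal-view construction)", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "FLCEP", "bone": "femur", "description": "Most lateral cartilage point of the lateral condyle at one third of the notch depth (coronal-view construction)", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "TMIE",  "bone": "tibia", "description": "Highest (most proximal) point of the medial intercondylar eminence", "refine_axis": "z", "refine_sense": "max", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "TLIE",  "bone": "tibia", "description": "Highest (most proximal) point of the lateral intercondylar eminence", "refine_axis": "z", "refine_sense": "max", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "TMCP",  "bone": "tibia", "description": "Most posterior (and lateral) point of the medial tibial compartment", "refine_axis": "y", "refine_sense": "min", "secondary_axis": "x", "secondary_sense": "max"},
    {"acronym": "TLCP",  "bone": "tibia", "description": "Most posterior (and medial) point of the lateral tibial compartment", "refine_axis": "y", "refine_sense": "min", "secondary_axis": "x", "secondary_sense": "min"},
    {"acronym": "TMCM",  "bone": "tibia", "description": "Most medial point of the tibial plateau, in the femur-derived axial alignment", "refine_axis": "x", "refine_sense": "min", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "TLCL",  "bone": "tibia", "description": "Most lateral point of the tibial plateau, in the femur-derived axial alignment", "refine_axis": "x", "refine_sense": "max", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "TMCA",  "bone": "tibia", "description": "Most anterior cartilage point of the medial tibial plateau (sagittal-view construction)", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"},
    {"acronym": "TLCA",  "bone": "tibia", "description": "Most anterior cartilage point of the lateral tibial plateau (sagittal-view construction)", "refine_axis": "none", "refine_sense": "none", "secondary_axis": "none", "secondary_sense": "none"}
  ]
}
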