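pt,soc
Basal cell carcinoma,Skin and subcutaneous tissue disorders
Squamous cell carcinoma of skin,Skin and subcutaneous tissue disorders
Malignant melanoma,Skin and subcutaneous tissue disorders
Malignant melanoma in situ,Skin and subcutaneous tissue disorders
Keratoacanthoma,Skin and subcutaneous tissue disorders
Bowen's disease,Skin and subcutaneous tissue disorders
Skin cancer,Skin and subcutaneous tissue disorders
Skin papilloma,Skin and subcutaneous tissue disorders
Melanocytic naevus,Skin and subcutaneous tissue disorders
Dysplastic naevus,Skin and subcutaneous tissue disorders
Lentigo maligna,Skin and subcutaneous tissue disorders
Merkel cell carcinoma,Skin and subcutaneous tissue disorders
Colon cancer,Gastrointestinal disorders
Colorectal cancer,Gastrointestinal disorders
Rectal cancer,Gastrointestinal disorders
Anal cancer,Gastrointestinal disorders
Gastric cancer,Gastrointestinal disorders
Oesophageal carcinoma,Gastrointestinal disorders
Pancreatic carcinoma,Gastrointestinal disorders
Colorectal adenoma,Gastrointestinal disorders
Colon neoplasm,Gastrointestinal disorders
Intestinal polyp,Gastrointestinal disorders
Gastrointestinal stromal tumour,Gastrointestinal disorders
Small intestine carcinoma,Gastrointestinal disorders
Lung neoplasm malignant,"Respiratory, thoracic and mediastinal disorders"
Lung adenocarcinoma,"Respiratory, thoracic and mediastinal disorders"
Non-small cell lung cancer,"Respiratory, thoracic and mediastinal disorders"
Small cell lung cancer,"Respiratory, thoracic and mediastinal disorders"
Bronchial carcinoma,"Respiratory, thoracic and mediastinal disorders"
Laryngeal cancer,"Respiratory, thoracic and mediastinal disorders"
Mesothelioma,"Respiratory, thoracic and mediastinal disorders"
Lymphoma,Blood and lymphatic system disorders
Hodgkin's disease,Blood and lymphatic system disorders
Non-Hodgkin's lymphoma,Blood and lymphatic system disorders
Diffuse large B-cell lymphoma,Blood and lymphatic system disorders
T-cell lymphoma,Blood and lymphatic system disorders
Hepatosplenic T-cell lymphoma,Blood and lymphatic system disorders
B-cell lymphoma,Blood and lymphatic system disorders
Acute myeloid leukaemia,Blood and lymphatic system disorders
Chronic lymphocytic leukaemia,Blood and lymphatic system disorders
Acute lymphocytic leukaemia,Blood and lymphatic system disorders
Myelodysplastic syndrome,Blood and lymphatic system disorders
Multiple myeloma,Blood and lymphatic system disorders
Leukaemia,Blood and lymphatic system disorders
Plasma cell myeloma,Blood and lymphatic system disorders
Renal cell carcinoma,Renal and urinary disorders
Bladder cancer,Renal and urinary disorders
Renal neoplasm,Renal and urinary disorders
Transitional cell carcinoma,Renal and urinary disorders
Hepatocellular carcinoma,Hepatobiliary disorders
Hepatic neoplasm malignant,Hepatobiliary disorders
Cholangiocarcinoma,Hepatobiliary disorders
Hepatic adenoma,Hepatobiliary disorders
Breast cancer,Reproductive system and breast disorders
Breast cancer female,Reproductive system and breast disorders
Prostate cancer,Reproductive system and breast disorders
Ovarian cancer,Reproductive system and breast disorders
Cervix carcinoma,Reproductive system and breast disorders
Uterine cancer,Reproductive system and breast disorders
Endometrial cancer,Reproductive system and breast disorders
Testicular cancer,Reproductive system and breast disorders
Vulval cancer,Reproductive system and breast disorders
Thyroid cancer,Endocrine disorders
Thyroid neoplasm,Endocrine disorders
Adrenal neoplasm,Endocrine disorders
Pituitary tumour,Endocrine disorders
Brain neoplasm,Nervous system disorders
Glioblastoma,Nervous system disorders
Meningioma,Nervous system disorders
Astrocytoma,Nervous system disorders
Osteosarcoma,Musculoskeletal and connective tissue disorders
Chondrosarcoma,Musculoskeletal and connective tissue disorders
Ewing's sarcoma,Musculoskeletal and connective tissue disorders
Liposarcoma,Musculoskeletal and connective tissue disorders
Metastases to liver,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Metastases to lung,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Metastases to bone,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Neoplasm malignant,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Neoplasm,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Benign neoplasm,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Tumour haemorrhage,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Kaposi's sarcoma,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
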