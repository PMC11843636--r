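pt,soc
Anemia,Blood and lymphatic system disorders
Vertigo,Ear and labyrinth disorders
Nausea,Gastrointestinal disorders
Abdominal pain (upper part),Gastrointestinal disorders
Abdominal pain,Gastrointestinal disorders
Abdominal pain (lower part),Gastrointestinal disorders
Retching,Gastrointestinal disorders
Fatigue,General disorders and administration site conditions
Pain,General disorders and administration site conditions
Edema peripheral,General disorders and administration site conditions
Feeling abnormal,General disorders and administration site conditions
Chills,General disorders and administration site conditions
Gait disturbance,General disorders and administration site conditions
Influenza like illness,General disorders and administration site conditions
Nasopharyngitis,Infections and infestations
Blood pressure decreased,Investigations
Blood creatinine increased,Investigations
Glomerular filtration rate decreased,Investigations
Blood pressure abnormal,Investigations
Hepatic enzyme increased,Investigations
Blood potassium increased,Investigations
Protein total decreased,Investigations
Gout,Metabolism and nutrition disorders
Arthralgia,Musculoskeletal and connective tissue disorders
Dizziness,Nervous system disorders
Somnolence,Nervous system disorders
Loss of consciousness,Nervous system disorders
Nasal congestion,"Respiratory, thoracic and mediastinal disorders"
Pruritus,Skin and subcutaneous tissue disorders
Hypotension,Vascular disorders
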