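pt	soc
Suicidal ideation	Psychiatric disorders
Suicide attempt	Psychiatric disorders
Completed suicide	Psychiatric disorders
Suicidal behavior	Psychiatric disorders
Suicide threat	Psychiatric disorders
Depression suicidal	Psychiatric disorders
Columbia suicide severity rating scale abnormal	Psychiatric disorders
Anxiety	Psychiatric disorders
Insomnia	Psychiatric disorders
Irritability	Psychiatric disorders
Anger	Psychiatric disorders
Depression	Psychiatric disorders
Agitation	Psychiatric disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Constipation	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Somnolence	Nervous system disorders
Tremor	Nervous system disorders
Disturbance in attention	Nervous system disorders
Fatigue	General disorders and administration site conditions
Asthenia	General disorders and administration site conditions
Feeling abnormal	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Pruritus	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Hyperhidrosis	Skin and subcutaneous tissue disorders
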