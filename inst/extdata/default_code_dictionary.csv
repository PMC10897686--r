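code,name,role,category,agent_class,min_daily_dose
AD001,citalopram,antidepressant,,,20
AD002,sertraline,antidepressant,,,50
AD003,fluoxetine,antidepressant,,,20
AD004,mirtazapine,antidepressant,,,15
AD005,venlafaxine,antidepressant,,,75
AD006,amitriptyline,antidepressant,,,75
AD007,paroxetine,antidepressant,,,20
AD008,duloxetine,antidepressant,,,60
AG001,lithium,augmentation_agent,,lithium,
AG002,quetiapine,augmentation_agent,,antipsychotic,
AG003,olanzapine,augmentation_agent,,antipsychotic,
AG004,aripiprazole,augmentation_agent,,antipsychotic,
AG005,levothyroxine,augmentation_agent,,thyroxine,
AG006,liothyronine,augmentation_agent,,tri_iodothyronine,
AG007,lamotrigine,augmentation_agent,,anticonvulsant,
AG008,valproate,augmentation_agent,,anticonvulsant,
DEP01,depressive episode,,depression,,
DEP02,recurrent depression,,depression,,
EXC01,bipolar affective disorder,,exclusion,,
EXC02,dementia,,exclusion,,
EXC03,mania,,exclusion,,
EXC04,psychosis,,exclusion,,
EXC05,schizophrenia,,exclusion,,
EXC06,schizoaffective disorder,,exclusion,,
COM01,anxiety disorder,,comorbidity,,
COM02,asthma,,comorbidity,,
COM03,alcohol or substance misuse,,comorbidity,,
COM04,diabetes mellitus,,comorbidity,,
SUI01,suicidal ideation,,suicidality,,
SUI02,suicide attempt,,suicidality,,
SUI03,self-harm,,suicidality,,
MHR01,referral to mental health services,,mhs_referral,,
MHC01,mental health service contact,,mhs_contact,,
ASM01,PHQ-9 assessment,,assessment,,
ASM02,GAD-7 assessment,,assessment,,
ASM03,AUDIT-C assessment,,assessment,,
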