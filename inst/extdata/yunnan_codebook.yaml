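# Codebook for the 2009 Yunnan PWID needle-sharing survey (20 categorical
# risk factors + binary sharing outcome). Category order follows the printed
# summary table; the first-listed (reference) category is marked explicitly.
# Roles drive node colouring in network exports: sociodemographic, drug_use,
# sexual_infectious.
outcome: "Shared needles"
factors:
  - name: "Residence"
    role: sociodemographic
    reference: "Baoshan"
    categories: ["Baoshan", "Zhaotong", "Qujing", "Dehong", "Lincang"]
  - name: "Gender"
    role: sociodemographic
    reference: "Male"
    categories: ["Male", "Female"]
  - name: "Age"
    role: sociodemographic
    reference: "13-25"
    categories: ["13-25", "26-30", "31-35", "36-68"]
  - name: "Ethnicity"
    role: sociodemographic
    reference: "Han"
    categories: ["Han", "Minority"]
  - name: "Occupation"
    role: sociodemographic
    reference: "Various jobs"
    categories: ["Various jobs", "Farmer", "Jobless"]
  - name: "Marital status"
    role: sociodemographic
    reference: "Unmarried"
    categories: ["Unmarried", "Married", "Cohabitated", "Divorced or widowed"]
  - name: "Education"
    role: sociodemographic
    reference: "None"
    categories: ["None", "1-5 years", "6-9 years", ">10 years"]
  - name: "Drug of choice"
    role: drug_use
    reference: "Heroin"
    categories: ["Heroin", "Heroin + others"]
  - name: "Other drug use"
    role: drug_use
    reference: "No"
    categories: ["No", "Diazepam", "Diazepam + others", "Other"]
  - name: "Method of drug intake"
    role: drug_use
    reference: "Injection"
    categories: ["Injection", "Injection + oral"]
  - name: "Duration of drug abuse"
    role: drug_use
    reference: "<5 years"
    categories: ["<5 years", "6-10 years", "11-15 years", "16-20 years"]
  - name: "Drug use frequency"
    role: drug_use
    reference: "<1"
    categories: ["<1", "2", "3", ">4"]
  - name: "Most recent drug use"
    role: drug_use
    reference: "<1 year"
    categories: ["<1 year", "1 year", ">2 years"]
  - name: "Duration of drug injection"
    role: drug_use
    reference: "<5 years"
    categories: ["<5 years", "6-10 years", ">11 years"]
  - name: "Source of syringe"
    role: drug_use
    reference: "Clinic"
    categories: ["Clinic", "Hospital", "Drugstore", "Other"]
  - name: "Times reusing needle"
    role: drug_use
    reference: "1"
    categories: ["1", "2", ">3"]
  - name: "Number of sexual partners"
    role: sexual_infectious
    reference: "None"
    categories: ["None", "1", "2-3", "4-6", "7-10", ">11"]
  - name: "STD diagnosis"
    role: sexual_infectious
    reference: "No"
    categories: ["No", "Yes"]
  - name: "HIV serostatus"
    role: sexual_infectious
    reference: "Negative"
    categories: ["Negative", "Positive"]
  - name: "Other infectious diseases"
    role: sexual_infectious
    reference: "No"
    categories: ["No", "Yes", "Unknown"]
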