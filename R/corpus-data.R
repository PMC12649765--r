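# Authored content for the synthetic knowledge base: 20 high-frequency
# postoperative recovery topics, each with 10 (question, fact) items. Facts
# carry explicit numerals (timings, doses, limits) so the
# numeric-fabrication gate is exercised; every fact is a single sentence
# that later serves as the gold passage for its paired question.

kb_topic_specs <- function() {
  it <- function(q, f) list(q = q, f = f)
  list(
    list(name = "Pain and Pain Management", items = list(
      it("How much acetaminophen can I take each day for pain?",
         "You may take acetaminophen 650 mg by mouth every 6 hours as needed for pain, up to 3000 mg in 24 hours."),
      it("When can I start taking ibuprofen after my operation?",
         "Unless told otherwise, you may start ibuprofen 400 mg with food every 8 hours beginning 24 hours after surgery."),
      it("How long should I use the prescribed opioid pills?",
         "Use the prescribed opioid pills only for severe pain and try to stop them within 3 to 5 days after surgery."),
      it("How often can I apply ice to the surgical area?",
         "Apply a cloth-wrapped ice pack to the surgical area for 20 minutes at a time, up to 5 times per day, during the first 72 hours."),
      it("When should my pain start to improve after surgery?",
         "Surgical pain is usually worst for the first 48 to 72 hours and then improves steadily over 1 to 2 weeks."),
      it("What can I do to reduce pain without more medication?",
         "Gentle position changes, short walks, and relaxation breathing every 2 hours can reduce pain without extra medication."),
      it("Should I take my pain medicine with food?",
         "Take pain medicine with a small snack and a full glass of water to protect your stomach."),
      it("What should I do if my pain medication causes constipation?",
         "If pain medication causes constipation, drink extra water and ask your care team about a stool softener once daily."),
      it("Is it okay to drink alcohol while taking pain medication?",
         "Do not drink alcohol while you are taking opioid or other sedating pain medication."),
      it("When should I call the clinic about my pain level?",
         "Call the clinic if pain scores stay above 7 out of 10 despite medication for more than 24 hours."))),
    list(name = "Postoperative Nausea and Vomiting (PONV)", items = list(
      it("Is it normal to feel queasy the day after anesthesia?",
         "Mild queasiness is common for 24 to 48 hours after anesthesia and usually settles on its own."),
      it("What medicine can I take for nausea at home?",
         "You may take ondansetron 4 mg under the tongue every 8 hours as needed for nausea."),
      it("How should I restart eating if I am vomiting?",
         "If you vomit, rest your stomach for 1 hour, then restart with clear liquids in small sips every 15 minutes."),
      it("Does ginger actually help with nausea after surgery?",
         "Ginger tea or ginger chews 2 to 3 times daily can ease mild nausea after surgery."),
      it("When should vomiting after surgery be reported?",
         "Report vomiting that lasts more than 24 hours or prevents you from keeping down fluids or medication."),
      it("What foods are easiest on my stomach right after surgery?",
         "Bland foods such as crackers, rice, bananas, and toast are easiest on your stomach for the first 2 days."),
      it("Can strong smells make postoperative nausea worse?",
         "Strong smells, greasy meals, and large portions commonly make postoperative nausea worse; eat small meals 5 to 6 times daily."),
      it("Why does riding in the car make me feel sick after surgery?",
         "Motion can aggravate nausea for about 1 week after anesthesia, so sit in the front seat and keep rides short."),
      it("Should I keep taking anti-nausea medicine once I feel better?",
         "Stop scheduled anti-nausea medicine once you have been free of nausea for 24 hours."),
      it("Does dehydration make nausea worse during recovery?",
         "Dehydration worsens nausea, so aim for at least 6 to 8 cups of fluid spread across the day."))),
    list(name = "Drain Management", items = list(
      it("How often do I need to empty my surgical drain?",
         "Empty your surgical drain every 8 to 12 hours, or sooner when the bulb is about half full."),
      it("How do I record the drain output each day?",
         "Record the drain output in milliliters in your log each time you empty it, and total the amount every 24 hours."),
      it("When will my drain output be low enough for the drain to be removed?",
         "Drains are usually removed once output stays below 30 mL per day for 2 days in a row."),
      it("How do I strip the drain tubing?",
         "Strip the drain tubing gently toward the bulb 2 to 3 times daily to keep the drain from clogging."),
      it("How do I keep suction in the drain bulb?",
         "After emptying the drain, squeeze the bulb flat and close the plug to restore suction."),
      it("How should I secure the drain so it does not pull?",
         "Pin or clip the drain bulb to your clothing below the exit site so the tubing never dangles or pulls."),
      it("What color should the drain fluid be during recovery?",
         "Drain fluid changes from red to pink to pale yellow over the first 5 to 7 days; a gradual change is expected."),
      it("Can I shower while the drain is still in place?",
         "You may shower 48 hours after surgery with the drain secured; do not submerge the drain site in a bath."),
      it("What should I do if the drain site leaks around the tube?",
         "A small amount of leakage around the drain tube can be covered with a dry gauze pad changed once daily."),
      it("When should I call about a problem with my drain?",
         "Call the clinic if drain output suddenly doubles, turns bright red, or stops completely for 8 hours."))),
    list(name = "Follow-up Appointments", items = list(
      it("When is my first follow-up visit after surgery?",
         "Your first follow-up visit is usually scheduled 7 to 10 days after surgery."),
      it("What should I bring to my follow-up appointment?",
         "Bring your medication list, your drain log, and a written list of questions to every follow-up appointment."),
      it("Can my follow-up be done by video instead of in person?",
         "Many routine follow-up checks can be done by video visit; confirm with the clinic 2 days ahead."),
      it("What happens when the team checks the incision at the first postoperative visit?",
         "At the first visit the team checks the incision, reviews your recovery, and adjusts medication if needed."),
      it("How do I reschedule a missed clinic visit?",
         "If you miss a visit, call the scheduling line within 1 business day to rebook."),
      it("How many follow-up visits will I have in the first year?",
         "Most patients have 3 to 4 follow-up visits during the first year after surgery."),
      it("When are the sutures and incision line checked after the operation?",
         "Sutures and the incision line are checked at the 7 to 10 day visit and again at 6 weeks."),
      it("Should someone drive me to my first follow-up visit?",
         "Arrange for someone to drive you to the first follow-up visit if you are still taking opioid medication."),
      it("How do I contact the clinic between appointments?",
         "Use the patient portal for routine questions between appointments; messages are answered within 1 business day."),
      it("When will lab tests be reviewed after surgery?",
         "Any lab tests drawn around surgery are reviewed with you at the first follow-up visit."))),
    list(name = "Postoperative Recovery and Recovery Timeline", items = list(
      it("How long will I feel tired after my operation?",
         "Fatigue is normal for 2 to 6 weeks after surgery and improves gradually with light daily activity."),
      it("When does swelling peak after surgery and how long until it slowly goes down?",
         "Swelling usually peaks 48 to 72 hours after surgery and then slowly goes down over 2 to 4 weeks."),
      it("How long does bruising take to fade?",
         "Bruising typically fades over 2 to 3 weeks, shifting from purple to green to yellow as it heals."),
      it("When will my usual energy return after surgery?",
         "Most people feel close to their usual energy by 6 to 8 weeks, though full recovery can take 3 months."),
      it("Should I nap during the day while recovering?",
         "Short naps of 20 to 30 minutes are fine; long daytime sleeping can make nighttime rest harder."),
      it("How much walking should I do in the first week?",
         "Walk for 5 to 10 minutes, 4 to 6 times daily, during the first week to support circulation and healing."),
      it("Is it normal for one side to heal faster than the other?",
         "Small differences in swelling and comfort between sides are common and usually even out by 6 weeks."),
      it("When can I expect numbness near the incision to improve?",
         "Patches of numbness near the incision are common and usually improve over 3 to 6 months."),
      it("Why do I feel emotional ups and downs while healing?",
         "Energy and mood often dip around day 3 to 5 of recovery; this is a normal part of early healing."),
      it("How can I track that my recovery is on schedule?",
         "Keep a simple daily note of pain, swelling, and activity; steady weekly improvement is the expected pattern."))),
    list(name = "Diet and Food to Eat After Surgery", items = list(
      it("What should I eat on the first day after surgery?",
         "Start with light foods such as soup, yogurt, and toast on the first day after surgery."),
      it("How much water should I drink each day while healing?",
         "Drink 8 to 10 cups of water daily while healing unless your team has told you to limit fluids."),
      it("How much protein do I need to support healing?",
         "Aim for 60 to 80 grams of protein daily from eggs, fish, poultry, beans, or dairy to support healing."),
      it("What can I eat to avoid constipation after surgery?",
         "Eat 25 to 30 grams of fiber daily from fruits, vegetables, and whole grains to prevent constipation."),
      it("When can I drink alcohol again after my operation?",
         "Avoid alcohol for at least 2 weeks after surgery and for as long as you take prescription pain medication."),
      it("Is extra salt bad for my recovery?",
         "Limit salty foods during the first 2 weeks of recovery because extra salt increases swelling."),
      it("Should I take a vitamin while I recover?",
         "A daily multivitamin with vitamin C and zinc is reasonable during the first month of healing."),
      it("Is caffeine allowed while I am recovering?",
         "Moderate caffeine, up to 2 cups of coffee daily, is fine once nausea has settled."),
      it("What if my appetite is small and I cannot face large meals after surgery?",
         "A small appetite is common for 1 to 2 weeks after surgery; eat small, frequent meals rather than forcing large ones."),
      it("Are there foods I should avoid completely at first?",
         "Avoid greasy, fried, and very spicy foods for the first week, as they commonly upset the stomach."))),
    list(name = "Resuming Physical Activity", items = list(
      it("When can I begin short walks after surgery?",
         "Begin short walks around your house on the day after surgery, increasing the distance a little each day."),
      it("How much weight can I lift during early recovery?",
         "Do not lift anything heavier than 10 pounds for the first 4 weeks after surgery."),
      it("When can I return to the gym for light cardio and weights?",
         "You may return to the gym for light cardio at 4 weeks and resume weights at 6 weeks if cleared at your visit."),
      it("When can I resume core and abdominal exercises?",
         "Hold off on core and abdominal exercises until 8 weeks after surgery."),
      it("How do I know if I have done too much activity?",
         "Increased swelling, throbbing, or drainage after activity means you did too much; rest for 24 hours and scale back."),
      it("Is swimming allowed before my incisions are fully healed?",
         "No swimming until incisions are fully healed and your team clears you, usually at 4 to 6 weeks."),
      it("When can I ride a stationary bike?",
         "A stationary bike at an easy pace is usually fine from week 2 if it causes no pulling at the incision."),
      it("How should I warm up before a workout when I restart exercise?",
         "Warm up with 5 to 10 minutes of easy walking and stretch gently before any workout in the first 3 months."),
      it("When can jogging resume after my operation?",
         "Jogging may resume around 6 weeks after surgery, starting at half your usual distance."),
      it("Are stairs safe in the first week after surgery?",
         "Stairs are fine from day 1; go slowly and use the handrail during the first week."))),
    list(name = "Scars", items = list(
      it("When should I begin scar massage after surgery?",
         "Begin scar massage 3 weeks after surgery, once the incision is fully closed, for 5 minutes 2 to 3 times daily."),
      it("How long do I need sunscreen on my scar?",
         "Protect the scar with SPF 30 or higher sunscreen for 12 months whenever it may be exposed to sun."),
      it("Do silicone sheets really help scars fade?",
         "Silicone sheets or gel, worn 12 hours daily for 2 to 3 months, can flatten and soften scars."),
      it("How long until my scar fades to its final color?",
         "Scars usually stay pink for 3 to 6 months and fade toward skin color over 12 to 18 months."),
      it("Is itching around a new scar expected?",
         "Mild itching around a maturing scar is common; a plain moisturizer applied twice daily usually relieves it."),
      it("Why does my scar look raised at one month?",
         "Scars often look raised and firm between weeks 3 and 8 before they gradually flatten."),
      it("What can I do to keep my scar soft?",
         "Keep the scar moisturized and avoid tension on the area for the first 6 weeks."),
      it("When can makeup be applied over the scar?",
         "Makeup may be applied over a fully closed scar after 3 weeks; remove it gently each night."),
      it("Will taping the incision help the scar?",
         "Paper tape worn across the incision line for 6 weeks can reduce scar stretching."),
      it("When should I ask about scar revision options?",
         "Wait at least 12 months before considering scar revision, since scars keep improving during the first year."))),
    list(name = "Sutures and Staples", items = list(
      it("Do my stitches dissolve or need removal?",
         "Dissolvable sutures soften and disappear on their own over 2 to 3 weeks; they do not need removal."),
      it("When are skin staples removed after surgery?",
         "Skin staples are usually removed at the clinic 10 to 14 days after surgery."),
      it("What are the little white strips over my incision?",
         "Steri-strips over the incision loosen and fall off on their own in 7 to 10 days; do not peel them off early."),
      it("Is it painful to have staples removed?",
         "Staple removal takes a few minutes and feels like small pinches; most people need no medication for it."),
      it("What if a suture end pokes out of the skin?",
         "A poking suture end can be trimmed at the clinic; do not pull on it at home."),
      it("Can I get the suture line wet when washing?",
         "You may let clean, soapy water run over the suture line in the shower after 48 hours, then pat it dry."),
      it("Should I put ointment on the suture line?",
         "Apply a thin layer of plain petroleum ointment to the suture line once daily after day 3 if it looks dry."),
      it("What holds the deeper layers of my incision together?",
         "Deeper layers are closed with buried dissolvable sutures that support the incision for about 6 weeks."),
      it("Why is there a small bump at the end of my incision?",
         "A small firm bump at the end of the incision is often a buried knot and usually settles by 8 weeks."),
      it("What happens if a staple comes loose early?",
         "If a staple loosens early, cover the area with a clean dressing and call the clinic for advice."))),
    list(name = "Sexual Activity", items = list(
      it("When is it safe to resume sexual activity after surgery?",
         "Sexual activity may usually be resumed gently 2 weeks after surgery if it causes no pain at the incision."),
      it("Which positions avoid pressure on the surgical area at first?",
         "Choose positions that avoid pressure or pulling on the surgical area for the first 6 weeks."),
      it("Why is my desire for intimacy lower after surgery?",
         "Lower desire is common for 4 to 6 weeks after surgery because of fatigue and medication; it returns with energy."),
      it("Can medication affect intimacy during recovery?",
         "Opioid medication can blunt desire and performance; this resolves after the medication is stopped."),
      it("Should I avoid intimacy while I still have a drain?",
         "Wait until drains are removed before resuming sexual activity."),
      it("Should I stop if I notice pulling or sharp twinges during intimacy?",
         "Stop and rest if you notice pulling, sharp twinges, or new swelling at the surgical site during intimacy."),
      it("Does scarring change sensation in the area?",
         "Skin near the incision may feel numb or oversensitive for 3 to 6 months; gentle touch helps it settle."),
      it("When should contraception be reviewed at a follow-up visit?",
         "Review contraception at the first follow-up visit, since some operations and medications change what is recommended."),
      it("Is it normal to feel anxious about intimacy after surgery?",
         "Feeling anxious about intimacy after surgery is common; going slowly and talking openly with your partner helps."),
      it("Does resuming intimacy affect how my incision heals?",
         "Gentle intimacy does not harm a healing incision; avoid direct strain on the area until 6 weeks."))),
    list(name = "Showering and Bathing", items = list(
      it("Can I take my first shower 48 hours after surgery?",
         "You may shower 48 hours after surgery unless your team gave you a different instruction."),
      it("How should I dry the incision after washing?",
         "After showering, pat the incision dry with a clean towel; do not rub it."),
      it("When can I soak in baths, hot tubs, or pools again?",
         "No baths, hot tubs, or pools until 3 weeks after surgery and until all incisions are fully closed."),
      it("Can soap touch my incision in the shower?",
         "Let mild soap and water run over the incision; do not scrub it directly for the first 2 weeks."),
      it("How hot can the shower water be?",
         "Use warm, not hot, water for the first week, since very hot showers can increase swelling and dizziness."),
      it("Should I cover the dressing while I wash?",
         "If you were told to keep the dressing dry, cover it with a plastic bag taped at the edges while you shower."),
      it("Should my first showers be short, and for how many minutes?",
         "Keep the first showers short, about 5 to 10 minutes, and have someone nearby in case you feel lightheaded."),
      it("When is hair washing fine after the operation?",
         "Hair washing is fine at 48 hours; a handheld shower head makes it easier in the first week."),
      it("Can I apply lotion near the incision after bathing?",
         "Apply lotion only to intact skin at least 1 inch away from the incision during the first 2 weeks."),
      it("Is a sponge bath enough before showers are allowed?",
         "Use a sponge bath to stay clean during the first 48 hours, keeping the dressing completely dry."))),
    list(name = "Emotional Wellbeing and Body Image", items = list(
      it("Is it normal to feel down in the first weeks after surgery?",
         "Mood dips are common during the first 2 weeks after surgery as energy and sleep recover."),
      it("Why do I feel teary for no clear reason while recovering?",
         "Anesthesia, disrupted sleep, and medication can make emotions swing for 1 to 2 weeks; this settles as routines return."),
      it("When will the surgical area look more normal to me?",
         "Swelling and bruising distort the early result; the area looks progressively more natural between weeks 3 and 12."),
      it("What can I do each day to support my mood?",
         "A short daily walk, sunlight, regular meals, and one social contact per day measurably support mood in recovery."),
      it("Should I look at my incision right away?",
         "Look at the surgical area when you feel ready; many people find day 3 to 7 a comfortable time to start."),
      it("What short sentence should I prepare for comments about my appearance?",
         "Prepare one short sentence you are comfortable saying, and remember that early appearance is not the final result."),
      it("When should low mood after surgery be discussed with a professional?",
         "If low mood lasts more than 2 weeks or stops you eating, washing, or sleeping, contact your care team."),
      it("Can I join a support group during recovery?",
         "Peer support groups, in person or online, help many patients from the second week of recovery onward."),
      it("Why do I compare my result to photos online?",
         "Online photos are often taken 6 to 12 months after surgery; comparing them to week 2 is misleading."),
      it("Does keeping a journal help during recovery?",
         "Writing a few lines daily about progress and worries lowers stress for many patients in the first month."))),
    list(name = "Sleep Disturbance", items = list(
      it("Should I sleep with my head and shoulders raised after surgery?",
         "Sleep on your back with your head and shoulders raised about 30 degrees for the first 2 weeks."),
      it("When can I sleep on my side again?",
         "You may usually return to side sleeping at 2 to 4 weeks if it causes no pulling at the incision."),
      it("Why do I keep waking up at night during recovery?",
         "Night waking is common for 1 to 2 weeks; take scheduled pain medicine before bed so discomfort does not wake you."),
      it("Should a pillow go under my knees to keep from rolling at night?",
         "Place a pillow under your knees and one at each side to keep from rolling during the night."),
      it("Is it okay to sleep in a recliner instead of a bed?",
         "A recliner is a good option for the first week if lying flat is uncomfortable."),
      it("What bedtime routine helps sleep while healing?",
         "Dim lights, no screens for 60 minutes before bed, and a fixed bedtime improve sleep during recovery."),
      it("Can I take an over-the-counter sleep aid?",
         "Ask your team before using sleep aids, because they can interact with prescribed pain medication."),
      it("Does napping too long affect my night sleep?",
         "Limit naps to 30 minutes and avoid napping after 3 pm so nighttime sleep stays solid."),
      it("When will I sleep normally again without discomfort?",
         "Most patients sleep normally again by 3 to 4 weeks as discomfort and medication taper off."),
      it("Should caffeine be limited to help sleep during recovery?",
         "Have no caffeine after noon while your sleep is disrupted in the first weeks of recovery."))),
    list(name = "Need for Home Assistance", items = list(
      it("How much help will I need at home after surgery?",
         "Plan for a helper at home around the clock for the first 72 hours after surgery."),
      it("What tasks should someone else handle in week one?",
         "Have someone else handle cooking, laundry, lifting, and driving during the first week."),
      it("When can I be safely alone during the day?",
         "Most patients can be alone for a few hours at a time from day 3 to 4 once walking is steady."),
      it("Should I prepare frozen meals and clear walkways before surgery?",
         "Before surgery, place daily items at waist height, prepare 5 to 7 frozen meals, and clear walkways of cords and rugs."),
      it("Can I lift my child during the first weeks after surgery?",
         "Arrange child care for the first week; do not lift a child heavier than 10 pounds for 4 weeks."),
      it("What about caring for pets during early recovery?",
         "Ask someone to walk dogs for 2 weeks; keep pets off your lap and away from the incision."),
      it("Should my helper come to the first follow-up visit?",
         "Bring your helper to the first visit so the instructions are heard by two sets of ears."),
      it("What equipment makes the first week easier?",
         "A shower chair, a reacher-grabber, and extra pillows make the first week at home noticeably easier."),
      it("Does insurance cover nursing visits if family cannot help?",
         "Ask the clinic about home health visits; many insurance plans cover 1 to 2 nursing visits after surgery."),
      it("When are light tasks like dusting and folding laundry fine again?",
         "Light tasks such as dusting or folding laundry are fine from week 2; save vacuuming for week 4."))),
    list(name = "Surgical Garments", items = list(
      it("How many hours a day do I wear the compression garment?",
         "Wear the compression garment 23 hours per day for the first 4 weeks, removing it only to wash."),
      it("When can I stop wearing the garment at night?",
         "After week 4, wear the garment during the day only, and stop night wear entirely at 6 weeks."),
      it("How do I wash the surgical garment?",
         "Hand wash the garment in cool water every 2 days and air dry it; keep a second garment to rotate."),
      it("How tight should the garment feel?",
         "The garment should feel snug and supportive, never numbing or painful; you should fit two fingers under the edge."),
      it("What if the garment rolls or folds at the edges?",
         "Smooth out rolls right away, since folded edges can press lines into healing skin within hours."),
      it("Can I switch to a lighter garment later?",
         "You may switch to a lighter support garment after week 4 if swelling is controlled."),
      it("How does steady compression help my skin settle evenly?",
         "Steady compression limits swelling and helps the skin settle evenly during the first 6 weeks."),
      it("Should padding go under the garment anywhere?",
         "Use only the foam pads your team provided; add nothing bulky under the garment without asking."),
      it("What do I do if the garment irritates my skin?",
         "For irritation, wear a thin cotton layer under the garment and check the skin twice daily."),
      it("Can I buy a replacement garment in a store?",
         "Replacement garments must match the compression grade you were fitted with; ask the clinic before buying."))),
    list(name = "Traveling", items = list(
      it("When can I drive a car again after surgery?",
         "You may drive again when you have stopped opioid medication for 24 hours and can brake hard without pain, usually 1 to 2 weeks."),
      it("When is it safe to fly on a plane after my operation?",
         "Short plane journeys are usually safe 2 weeks after surgery; discuss long-haul plans at your follow-up visit."),
      it("What should I do on a long car ride during recovery?",
         "On long car rides, stop every 60 to 90 minutes to walk for 5 minutes and keep fluids handy."),
      it("How do I lower clot risk while traveling?",
         "During any travel over 2 hours, pump your ankles regularly, walk hourly, and stay well hydrated to lower clot risk."),
      it("Can I wear my seatbelt comfortably after surgery?",
         "Always wear the seatbelt; a small folded towel between the belt and your body protects the surgical area."),
      it("Should I carry my medication while traveling?",
         "Carry medication in its original labeled containers in your hand luggage, with 2 extra days of doses."),
      it("Is it wise to travel far in the first week?",
         "Stay within 1 hour of the clinic for the first week in case you have questions that need a visit."),
      it("Should I travel with a summary of my operation and my surgeon's phone number?",
         "Travel with a summary of your operation and your surgeon's phone number for the first 6 weeks."),
      it("When can I take a long vacation after my operation?",
         "Plan long vacations for after the 6 week visit, when restrictions are usually lifted."),
      it("Do compression stockings help when I travel?",
         "Knee-high compression stockings during travel over 4 hours are recommended for the first 6 weeks."))),
    list(name = "Additional Treatments", items = list(
      it("When does radiation usually begin once incisions have healed?",
         "If radiation is part of your plan, it usually begins 4 to 6 weeks after surgery, once incisions have healed."),
      it("How soon can chemotherapy start once my lab results are back?",
         "Chemotherapy, when needed, commonly starts 3 to 6 weeks after surgery depending on healing and lab results."),
      it("Who coordinates my treatments after surgery?",
         "Your surgical team and oncology team coordinate the treatment calendar at a joint review in week 2 or 3."),
      it("Will radiation affect my scar?",
         "Radiation can make the scar and nearby skin darker and firmer; daily moisturizer and sun protection help."),
      it("Can physical therapy overlap with other treatments?",
         "Physical therapy can usually continue during additional treatments, with sessions adjusted to your energy."),
      it("What labs are checked before additional treatment?",
         "Blood counts and wound healing are checked about 1 week before any additional treatment begins."),
      it("Should I keep wearing my garment during radiation?",
         "Ask the radiation team before wearing compression over the treated area; a lighter garment is often advised."),
      it("How do extra treatments change my activity limits?",
         "Activity limits are reassessed when additional treatment starts; fatigue may require scaling plans back by half."),
      it("Whom do I call with side effects between visits?",
         "Call the team that prescribed a treatment for its side effects, and the surgical team for incision concerns."),
      it("Can supplements interfere with my additional treatment?",
         "Tell your team about every supplement you take, because some interfere with treatment and healing."))),
    list(name = "Alarm Signs", items = list(
      it("What incision changes mean I should call the clinic?",
         "Call the clinic for growing redness, warmth, or new drainage at the incision."),
      it("What temperature reading should make me call after surgery?",
         "Call if your temperature reaches 100.4 degrees Fahrenheit or higher on two readings taken 4 hours apart."),
      it("Which symptoms need a call on the same day?",
         "Same-day calls are needed for worsening pain, a fast-growing bruise, or swelling that increases after day 3."),
      it("How quickly should I report new leg soreness or warmth?",
         "Report new one-sided leg pain, warmth, or swelling the same day, since these can signal a clot."),
      it("Is redness beyond 1 centimeter from the incision edge a sign of infection?",
         "An infection often starts with spreading redness beyond 1 centimeter from the incision edge plus increasing tenderness."),
      it("Should thick or discolored drainage be reported?",
         "Drainage that becomes thick, discolored, or bad-smelling should be reported within 24 hours."),
      it("Are there medication reactions I should report at once?",
         "Report a new rash, severe itching, or swelling of the lips or tongue immediately and stop the medication."),
      it("Should I call about vomiting or no bowel movement by day 4?",
         "Call for vomiting beyond 24 hours, no bowel movement by day 4, or new severe abdominal pain."),
      it("When should bleeding at the incision be reported?",
         "A few spots of blood on the dressing are normal; report any bleeding that requires changing the dressing more than twice in a day."),
      it("Is the after-hours line in my discharge papers answered at night?",
         "The after-hours line on page 1 of your discharge papers is answered 24 hours a day, 7 days a week."))),
    list(name = "Wound Care", items = list(
      it("How long must the incision stay completely dry?",
         "Keep the incision completely dry for the first 48 hours after surgery."),
      it("How often should the dressing be changed?",
         "Change the outer dressing once daily and whenever it becomes wet or soiled."),
      it("How do I clean around the incision?",
         "Wash your hands for 20 seconds, then clean around the incision with mild soap and water and pat it dry."),
      it("Should I use antibiotic ointment on the wound?",
         "Apply a thin layer of antibiotic ointment once daily only if your team instructed it."),
      it("When can the incision be left open to air?",
         "Once the incision is dry and sealed, usually by day 5 to 7, it may be left open to air during the day."),
      it("Is a little clear fluid from the incision normal?",
         "A small amount of clear or slightly pink fluid on the dressing is normal in the first 3 days."),
      it("What supplies should I keep for dressing changes?",
         "Keep gauze pads, paper tape, and clean scissors in one labeled box, enough for 10 days of changes."),
      it("Can I scratch near the healing incision?",
         "Do not scratch the incision; press a clean cloth gently around it or use the moisturizer your team approved."),
      it("How tight should tape be over the dressing?",
         "Tape should hold the dressing flat without wrinkling the skin; painful tape is too tight."),
      it("How do I protect the incision from my waistband?",
         "Pad the incision with a single gauze layer if clothing rubs against it during the first 2 weeks."))),
    list(name = "Return to Work", items = list(
      it("When can I go back to a desk job?",
         "Most people return to a desk job 1 to 2 weeks after surgery."),
      it("How long before I can do physical work again?",
         "Physically demanding jobs usually require 4 to 6 weeks off, with lifting limits put in writing."),
      it("Can I work from my computer during the first week?",
         "Short computer sessions of 30 to 45 minutes with breaks are fine from day 3 to 4."),
      it("How do I get a work note for my employer?",
         "Request a work note through the patient portal; it is ready within 2 business days."),
      it("Does a half-day schedule ease the transition back to work?",
         "A half-day schedule for the first week back at work eases the transition and reduces setbacks."),
      it("What if my job requires standing all day?",
         "For standing jobs, ask about a stool and take a 5 minute sitting break every hour during the first month back."),
      it("Should job-related travel wait until the 6 week visit?",
         "Job-related travel should wait until the 6 week visit unless cleared earlier."),
      it("Are there tasks to avoid when I first return to work?",
         "Avoid lifting over 10 pounds, long ladders, and overnight shifts during the first month back."),
      it("What if pain returns at the end of a workday?",
         "Aching at the end of a workday usually means too many hours too soon; shorten the next 2 days and reassess."),
      it("Does my employer need details of my operation?",
         "Employers need only your restrictions and dates, not medical details; the work note covers this."))))
}

# Out-of-scope base queries: four non-medical families (finance, travel
# booking, entertainment, tech support), 10 each. Deliberately free of
# medical-lexicon tokens and of knowledge-base topic vocabulary.
oos_base_queries <- function() {
  c("What's the best stock to buy right now?",
    "How do I open a savings account online?",
    "Can you explain how index funds differ from mutual funds?",
    "What is the current mortgage interest rate?",
    "How do I file my taxes before the deadline?",
    "Is cryptocurrency a sensible investment this year?",
    "How can I raise my credit score quickly?",
    "Which budget app is good for tracking spending?",
    "How much should I put aside for retirement each month?",
    "How do I dispute a charge on my credit card?",
    "How do I upgrade to a window seat on my flight?",
    "What is the cheapest season for a holiday in Italy?",
    "Can I get a refund on a nonrefundable hotel reservation?",
    "Which airline has the best frequent flyer program?",
    "Is a visa required to visit Japan as a tourist?",
    "How early should I arrive at the airport for an international departure?",
    "What's the baggage allowance for economy class?",
    "How do I rent a vehicle at the airport without a credit card?",
    "Where can I find last-minute cruise deals?",
    "Is trip insurance worth buying for a short vacation?",
    "Who won the football match last night?",
    "What are the top movies streaming this weekend?",
    "When does the next season of that detective series come out?",
    "Which band is headlining the festival this summer?",
    "What video game should I play next?",
    "How do I get tickets to the playoff game?",
    "Who is favored to win the championship this year?",
    "What board games are fun for a family evening?",
    "Which streaming service has the best documentaries?",
    "What novels made the bestseller list this month?",
    "My laptop won't connect to the wifi, how do I fix it?",
    "How do I reset my email password?",
    "Why is my phone battery dying so fast?",
    "How do I back up my pictures to the cloud?",
    "My printer keeps jamming, what should I do?",
    "How do I update the software on my tablet?",
    "What's a good way to speed up an old computer?",
    "How do I move my address book to a new phone?",
    "Why does my smart TV keep buffering?",
    "How do I set up a wifi router in my apartment?")
}

# Emergency escalation base scenarios, each built around at least one
# red-flag lexicon phrase.
escalation_base_queries <- function() {
  c("I suddenly have trouble breathing and my chest feels tight.",
    "Blood is soaking through my bandage and the bleeding won't stop.",
    "I have crushing chest pain that started an hour ago.",
    "My temperature is 103 and I have a high fever with shaking chills.",
    "My husband fainted in the bathroom and is hard to wake.",
    "There are red streaks spreading up my arm from the incision.",
    "My left calf is swollen, hot, and painful when I walk.",
    "I feel like I can't breathe when I lie down tonight.",
    "There is foul-smelling drainage pouring from my wound since this morning.",
    "I blacked out for a moment when I stood up and my heart is racing.")
}
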